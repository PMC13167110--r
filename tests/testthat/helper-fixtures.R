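# Shared fixtures built once per test run.

default_lib <- build_reference_library()
injected_labels <- setdiff(default_lib$labels, "GCaMP6s")

# hand-built beta vector for classifier unit tests
make_beta <- function(raw, norm = raw, roi_id = "roi") {
  structure(list(beta_raw = raw, beta_norm = norm,
                 residual = 0, roi_id = roi_id),
            class = "beta_vector")
}

# hand-built assignment for metric unit tests
make_assignment <- function(roi_id, hits = character(), primary = NA_character_,
                            pass_id = 1L) {
  structure(list(roi_id = roi_id, hits = hits, primary = primary,
                 secondaries = setdiff(hits, primary), pass_id = pass_id,
                 z_raw = numeric(), z_norm = numeric()),
            class = "assignment_result")
}

# smooth random test image with structure at several scales
random_test_image <- function(n, seed) {
  set.seed(seed)
  img <- matrix(rnorm(n * n), n, n)
  as.matrix(EBImage::gblur(img, sigma = 2)) + 0.1 * matrix(rnorm(n * n), n, n)
}
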