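test_that("simulation configs validate their fields", {
  expect_error(simulation_config(c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(simulation_config(equal_distribution(c("a", "b")), snr = 0),
               "snr")
  expect_error(simulation_config(setNames(0.5, NULL)), "named")
  cfg <- realistic_config()
  expect_equal(cfg$gcamp_fraction, 0.30)
  expect_equal(cfg$background_fraction, 0.30)
  expect_equal(cfg$snr, 6)
  expect_equal(sum(realistic_distribution()), 1, tolerance = 1e-12)
})

test_that("unperturbed datasets are exact scaled references", {
  cfg <- simulation_config(equal_distribution(default_lib$labels),
                           n_rois = 40, snr = Inf, seed = 51)
  sim <- simulate_roi_dataset(cfg, default_lib)
  An <- sweep(default_lib$matrix, 2, apply(default_lib$matrix, 2, max), "/")
  for (i in c(1, 20, 40)) {
    expected <- sim$truth$amplitude[i] * An[, sim$truth$class[i]]
    expect_equal(unname(sim$spectra[, i]), unname(expected),
                 tolerance = 1e-12)
  }
})

test_that("the same seed reproduces the dataset bit for bit", {
  cfg <- realistic_config(n_rois = 80, seed = 52)
  s1 <- simulate_roi_dataset(cfg, default_lib)
  s2 <- simulate_roi_dataset(cfg, default_lib)
  expect_identical(s1$spectra, s2$spectra)
  expect_identical(s1$truth, s2$truth)
})

test_that("generated noise has the configured SD", {
  cfg <- simulation_config(equal_distribution(default_lib$labels),
                           n_rois = 10000, snr = 5, seed = 53)
  noisy <- simulate_roi_dataset(cfg, default_lib)
  clean_cfg <- cfg; clean_cfg$snr <- Inf
  clean <- simulate_roi_dataset(clean_cfg, default_lib)
  expect_identical(noisy$truth$class, clean$truth$class)
  target_sd <- mean(clean$truth$amplitude) / 5
  diff <- noisy$spectra - clean$spectra
  # measure away from the zero-clipping region
  unclipped <- clean$spectra > 3 * target_sd
  expect_equal(sd(diff[unclipped]), target_sd, tolerance = 0.02)
})

test_that("perturbation terms require their ingredients", {
  lib9 <- subset_library(default_lib, injected_labels)
  cfg <- simulation_config(equal_distribution(injected_labels),
                           gcamp_fraction = 0.3, seed = 1)
  expect_error(simulate_roi_dataset(cfg, lib9), "GCaMP6s")
  # dual labels are two distinct fluorophores
  dcfg <- simulation_config(equal_distribution(default_lib$labels),
                            n_rois = 100, dual_label = TRUE, seed = 54)
  sim <- simulate_roi_dataset(dcfg, default_lib)
  expect_true(all(sim$truth$class != sim$truth$class2))
  # second-fluorophore background differs from the primary
  bcfg <- simulation_config(equal_distribution(injected_labels),
                            n_rois = 100, background_fraction = 0.5,
                            background_mode = "second_fluorophore", seed = 55)
  sim2 <- simulate_roi_dataset(bcfg, default_lib)
  expect_true(all(sim2$truth$contaminant != sim2$truth$class))
})

test_that("metrics match a hand-enumerated confusion table", {
  truth <- data.frame(
    roi_id = paste0("r", 1:10),
    class = c("A", "A", "B", "B", "C", "C", "A", "B", "A", "B"),
    class2 = c(rep(NA, 8), "B", "C"),
    stringsAsFactors = FALSE)
  res <- list(
    make_assignment("r1", "A", "A"),       # correct
    make_assignment("r2", "B", "B"),       # false positive
    make_assignment("r3", character()),    # false negative
    make_assignment("r4", "B", "B"),       # correct
    make_assignment("r5", c("C", "A"), "C"),  # correct
    make_assignment("r6", "A", "A"),       # false positive
    make_assignment("r7", "A", "A"),       # correct
    make_assignment("r8", character()),    # false negative
    make_assignment("r9", "A", "A"),       # dual: one of {A,B}
    make_assignment("r10", c("B", "C", "A"), "B"))  # dual: both + extra
  m <- evaluate_assignments(res, truth)
  expect_equal(unname(m$single["accuracy"]), 4 / 8)
  expect_equal(unname(m$single["false_negative_rate"]), 2 / 8)
  expect_equal(unname(m$single["false_positive_rate"]), 2 / 8)
  expect_equal(sum(m$single[c("accuracy", "false_negative_rate",
                              "false_positive_rate")]), 1)
  expect_equal(unname(m$dual["at_least_one"]), 1)
  expect_equal(unname(m$dual["both"]), 1 / 2)
  expect_equal(unname(m$dual["secondary_fp"]), 1 / 2)
  pf <- m$per_fluorophore
  # single-label A rows are r1 (correct), r2 (FP), r7 (correct)
  expect_equal(pf$accuracy[pf$fluorophore == "A"], 2 / 3)
  # truth pair {A,B} with result {A}: found one, not both, no false hit
  m2 <- evaluate_assignments(list(make_assignment("r9", "A", "A")),
                             truth[9, ])
  expect_equal(unname(m2$dual), c(1, 0, 0, 1))
  expect_error(evaluate_assignments(res[1:9], truth), "ids")
})

test_that("metrics are invariant under consistent fluorophore relabeling", {
  truth <- data.frame(roi_id = paste0("r", 1:4),
                      class = c("A", "B", "A", "B"),
                      class2 = NA_character_, stringsAsFactors = FALSE)
  res <- list(make_assignment("r1", "A", "A"),
              make_assignment("r2", "A", "A"),
              make_assignment("r3", character()),
              make_assignment("r4", "B", "B"))
  m1 <- evaluate_assignments(res, truth)
  swap <- c(A = "B", B = "A")
  truth2 <- truth; truth2$class <- unname(swap[truth$class])
  res2 <- lapply(res, function(a) {
    a$hits <- unname(swap[a$hits])
    if (!is.na(a$primary)) a$primary <- unname(swap[a$primary])
    a
  })
  m2 <- evaluate_assignments(res2, truth2)
  expect_equal(m1$single, m2$single)
})

test_that("accuracy degrades no faster than replicate noise as SNR falls", {
  cfg <- simulation_config(equal_distribution(injected_labels),
                           n_rois = 200, seed = 60)
  sw <- run_sweep(cfg, "snr", values = c(12, 3), library = default_lib,
                  candidates = injected_labels, replicates = 6)
  s <- summarize_sweep(sw)
  hi <- s$accuracy_mean[s$value == 12]
  lo <- s$accuracy_mean[s$value == 3]
  expect_gt(hi, lo - 2 * max(s$accuracy_sd))
})

test_that("dual-pass strictly improves dominant recovery at 80% prevalence", {
  p <- c(0.8, rep(0.2 / 9, 9))
  names(p) <- c("mVenus", setdiff(default_lib$labels, "mVenus"))
  single <- dual <- numeric(4)
  for (i in 1:4) {
    cfg <- simulation_config(p, n_rois = 300, seed = 70 + i)
    sim <- simulate_roi_dataset(cfg, default_lib)
    for (dp in c(FALSE, TRUE)) {
      cl <- classify_subject(sim$spectra, default_lib, dual_pass = dp)
      m <- evaluate_assignments(cl, sim$truth)
      pf <- m$per_fluorophore
      acc <- pf$accuracy[pf$fluorophore == "mVenus"]
      if (dp) dual[i] <- acc else single[i] <- acc
    }
  }
  expect_true(all(dual > single))
})

test_that("simulated image pairs are reproducible and carry coherent truth", {
  p1 <- simulate_image_pair(seed = 81, default_lib, render_stacks = FALSE)
  p2 <- simulate_image_pair(seed = 81, default_lib, render_stacks = FALSE)
  expect_identical(p1$miniscope, p2$miniscope)
  expect_identical(p1$reference, p2$reference)
  expect_equal(names(p1$masks), p1$truth$roi_id)
  # a cell-free scene still registers on the vasculature alone
  p0 <- simulate_image_pair(seed = 82, default_lib, n_cells = 0,
                            render_stacks = FALSE)
  r <- register_images(p0$reference, p0$miniscope,
                       grid = search_grid(coarse_stride = 4))
  expect_lt(abs(r$transform$tx - 10), 1)
  expect_lt(abs(r$transform$ty + 15), 1)
  expect_lt(abs(r$transform$rotation - 5), 0.5)
  expect_lt(abs(r$transform$scale - 1.9), 0.01)
})
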