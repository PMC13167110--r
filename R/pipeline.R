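#' Read / write a run configuration
#'
#' YAML round trip of the full pipeline configuration: input paths (per-
#' laser stacks, miniscope image, ROI masks, traces, events), grid and
#' library settings, registration search grid, unmixing options, behavior
#' window, seed, and output directory.
#'
#' @param path YAML path.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @param config named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

default_run_config <- function(out_dir) {
  list(
    stacks = list(),              # laser nm (character) -> TIFF path
    stack_layout = list(n_z = 2, n_bins = 34, pixel_size = 3, z_step = 5),
    miniscope = NULL, masks = NULL, library = NULL,
    traces = NULL, events = NULL,
    z_crop = NULL, rolling_ball_um = 30,
    registration = list(translation = c(60, 5), rotation = c(15, 5),
                        scale = c(1.8, 2.0, 0.05), learning_rate = 0.5,
                        coarse_stride = 2),
    unmixing = list(k = 1.5, dual_pass = TRUE),
    behavior = list(fs = 20, window = 2.5, alpha = 0.05),
    seed = 1, out_dir = out_dir)
}

stage_log <- function(manifest, stage, status, detail = "") {
  manifest$stages[[stage]] <- list(status = status, detail = detail,
                                   time = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  message(sprintf("[%s] %s %s", stage, status, detail))
  manifest
}

#' Run the full identification pipeline from one config
#'
#' Stages, in order: flatten the per-laser spectral stacks (rolling-ball
#' background subtraction + summed z-projection), register the miniscope
#' image to the confocal reference channel, map the ROI masks into confocal
#' coordinates, extract per-ROI fingerprints, classify identities with the
#' dual-pass thresholds, and (when traces/events are configured) test
#' behavioral selectivity. Every intermediate is written to the output
#' directory together with a manifest recording parameters, seed, and
#' per-stage status. A failed stage is recorded and later stages skipped.
#'
#' @param config a run-config list (see [read_run_config()]) or a YAML
#'   path.
#' @return the manifest (invisibly also written to `manifest.yaml`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed %||% 1)
  manifest <- list(package_version = as.character(utils::packageVersion("plexid")),
                   seed = config$seed, parameters = config, stages = list())
  fail <- function(stage, e) {
    manifest <<- stage_log(manifest, stage, "failed", conditionMessage(e))
    yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
    manifest
  }

  # --- libraries and grid -------------------------------------------------
  library_obj <- tryCatch({
    if (is.null(config$library)) build_reference_library()
    else read_fingerprints(config$library)
  }, error = function(e) e)
  if (inherits(library_obj, "error")) return(fail("library", library_obj))
  grid <- library_obj$grid
  manifest <- stage_log(manifest, "library",
                        "complete", sprintf("%d fluorophores",
                                            length(library_obj$labels)))

  # --- flatten ------------------------------------------------------------
  flat <- tryCatch({
    lay <- config$stack_layout
    if (length(config$stacks) == 0) stop("no spectral stacks configured")
    fl <- list()
    ref_raw <- NULL
    for (nm in names(config$stacks)) {
      st <- read_stack_tiff(config$stacks[[nm]], lay$n_z, lay$n_bins,
                            as.numeric(nm), lay$pixel_size, lay$z_step)
      fl[[nm]] <- flatten_stack(st, z_crop = unlist(config$z_crop),
                                radius_um = config$rolling_ball_um)
      # registration uses the raw summed projection: the rolling ball
      # removes the broad vascular contrast that registration relies on
      if (is.null(ref_raw)) {
        raw <- flatten_stack(st, z_crop = unlist(config$z_crop),
                             radius_um = NULL)
        ref_bin <- which.min(abs(bin_centers(grid) - 512))
        ref_raw <- raw[ref_bin, , ]
      }
    }
    list(flattened = fl, reference = ref_raw)
  }, error = function(e) e)
  if (inherits(flat, "error")) return(fail("flatten", flat))
  reference <- flat$reference
  flat <- flat$flattened
  manifest <- stage_log(manifest, "flatten", "complete",
                        sprintf("%d lasers", length(flat)))

  # --- register -----------------------------------------------------------
  reg <- tryCatch({
    mini <- read_image_tiff(config$miniscope)
    rg <- config$registration
    g <- search_grid(unlist(rg$translation), unlist(rg$rotation),
                     unlist(rg$scale), rg$learning_rate, rg$coarse_stride)
    r <- register_images(reference, mini, g)
    write_transform(r$transform, file.path(out, "transform.yaml"), r$score)
    r
  }, error = function(e) e)
  if (inherits(reg, "error")) return(fail("register", reg))
  manifest <- stage_log(manifest, "register", "complete",
                        sprintf("score %.3f", reg$score))

  # --- extract ------------------------------------------------------------
  spectra <- tryCatch({
    masks <- read_roi_masks(config$masks)
    ref_dim <- dim(flat[[1]])[2:3]
    mini_dim <- dim(read_image_tiff(config$miniscope))
    warped <- lapply(masks, apply_transform, t = reg$transform,
                     mode = "nearest", out_dim = ref_dim,
                     src_dim = mini_dim)
    fps <- lapply(warped, extract_roi_spectrum,
                  flattened_per_laser = flat, grid = grid)
    S <- vapply(fps, flatten_fingerprint, numeric(grid$n_lasers * grid$n_bins))
    colnames(S) <- vapply(fps, function(f) as.character(f$label), character(1))
    write_spectra(S, grid, file.path(out, "roi_spectra.tsv"))
    S
  }, error = function(e) e)
  if (inherits(spectra, "error")) return(fail("extract", spectra))
  manifest <- stage_log(manifest, "extract", "complete",
                        sprintf("%d ROIs", ncol(spectra)))

  # --- unmix --------------------------------------------------------------
  cls <- tryCatch({
    u <- config$unmixing
    cl <- classify_subject(spectra, library_obj, k = u$k %||% 1.5,
                           dual_pass = isTRUE(u$dual_pass),
                           candidates = unlist(u$candidates))
    write.table(assignments_table(cl), file.path(out, "assignments.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    cl
  }, error = function(e) e)
  if (inherits(cls, "error")) return(fail("unmix", cls))
  manifest <- stage_log(manifest, "unmix", "complete",
                        sprintf("%d assigned of %d",
                                sum(!is.na(vapply(cls$assignments,
                                                  function(a) a$primary,
                                                  character(1)))),
                                length(cls$assignments)))

  # --- behavior (optional) ------------------------------------------------
  if (!is.null(config$traces) && !is.null(config$events)) {
    beh <- tryCatch({
      traces <- read.delim(config$traces, check.names = FALSE)
      events <- read.delim(config$events)
      bh <- config$behavior
      st <- selectivity_table(traces, events, fs = bh$fs,
                              window = bh$window, alpha = bh$alpha)
      write.table(st, file.path(out, "selectivity.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      st
    }, error = function(e) e)
    if (inherits(beh, "error")) return(fail("behavior", beh))
    manifest <- stage_log(manifest, "behavior", "complete",
                          sprintf("%d selective", sum(beh$selective)))
  }

  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate ready-to-use input fixtures
#'
#' Writes synthetic inputs consumable by every other entry point:
#' `"fingerprints"` a reference library table; `"roi_dataset"` simulated
#' ROI spectra plus ground truth under the realistic preset;
#' `"image_pair"` per-laser stacks, miniscope image, ROI masks and a run
#' config wired to them.
#'
#' @param kind one of `"fingerprints"`, `"roi_dataset"`, `"image_pair"`.
#' @param seed integer seed.
#' @param out output directory.
#' @return (invisibly) the paths written.
#' @export
make_fixtures <- function(kind = c("fingerprints", "roi_dataset",
                                   "image_pair"),
                          seed = 1, out = ".") {
  kind <- tryCatch(match.arg(kind), error = function(e)
    stop("unknown fixture kind; valid kinds: fingerprints, roi_dataset, ",
         "image_pair", call. = FALSE))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  lib <- build_reference_library()
  paths <- character()
  if (kind == "fingerprints") {
    paths <- file.path(out, "reference_library.tsv")
    write_fingerprints(lib, paths)
  } else if (kind == "roi_dataset") {
    cfg <- realistic_config(seed = seed)
    sim <- simulate_roi_dataset(cfg, lib)
    paths <- file.path(out, c("roi_spectra.tsv", "roi_truth.tsv",
                              "reference_library.tsv"))
    write_spectra(sim$spectra, lib$grid, paths[1])
    write.table(sim$truth, paths[2], sep = "\t", row.names = FALSE,
                quote = FALSE)
    write_fingerprints(lib, paths[3])
  } else {
    pair <- simulate_image_pair(seed, lib)
    stack_paths <- file.path(out, sprintf("stack_%s.tif", names(pair$stacks)))
    for (i in seq_along(pair$stacks))
      write_stack_tiff(pair$stacks[[i]], stack_paths[i])
    mini_path <- file.path(out, "miniscope.tif")
    write_image_tiff(pair$miniscope, mini_path)
    mask_path <- file.path(out, "roi_masks.tsv")
    write_roi_masks(pair$masks, mask_path)
    lib_path <- file.path(out, "reference_library.tsv")
    write_fingerprints(lib, lib_path)
    truth_path <- file.path(out, "truth.tsv")
    write.table(pair$truth, truth_path, sep = "\t", row.names = FALSE,
                quote = FALSE)
    cfg <- default_run_config(file.path(out, "run"))
    cfg$stacks <- as.list(stats::setNames(stack_paths, names(pair$stacks)))
    d <- dim(pair$stacks[[1]]$values)
    cfg$stack_layout <- list(n_z = d[1], n_bins = d[2],
                             pixel_size = pair$stacks[[1]]$pixel_size,
                             z_step = pair$stacks[[1]]$z_step)
    cfg$miniscope <- mini_path
    cfg$masks <- mask_path
    cfg$library <- lib_path
    cfg$unmixing$candidates <- setdiff(lib$labels, "GCaMP6s")
    cfg$seed <- seed
    cfg_path <- file.path(out, "run_config.yaml")
    write_run_config(cfg, cfg_path)
    paths <- c(stack_paths, mini_path, mask_path, lib_path, truth_path,
               cfg_path)
  }
  invisible(paths)
}
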