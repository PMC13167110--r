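#' Simulate a co-registered confocal/miniscope image pair
#'
#' End-to-end fixture generator: renders a shared vessel scene with
#' fluorophore-labelled somata in confocal coordinates, emits per-laser
#' spectral z-stacks, and produces the corresponding time-averaged
#' miniscope image related to the confocal frame by a known similarity
#' transform (miniscope -> confocal). ROI masks are returned in miniscope
#' coordinates, as a calcium-segmentation step would deliver them.
#'
#' @param seed integer seed.
#' @param library a `reference_library` (max-one normalized references are
#'   used for rendering).
#' @param transform the true miniscope-to-confocal `similarity_transform`.
#' @param confocal_dim,miniscope_dim image sizes `c(rows, cols)`.
#' @param n_cells number of labelled somata.
#' @param n_vessels number of vessel random walks.
#' @param cell_radius soma radius in confocal pixels.
#' @param snr peak soma amplitude over confocal noise SD.
#' @param n_z z planes per stack (the soma/vessel signal is split evenly
#'   across planes, emulating the chromatic focal spread the summed
#'   projection removes).
#' @param classes fluorophore labels assigned to somata (default: all
#'   non-GCaMP labels, cycled).
#' @param render_stacks set `FALSE` to skip rendering the spectral stacks
#'   (registration-only fixtures; `stacks` is then empty and `reference`
#'   is derived from the scene directly).
#' @return list with `stacks` (named list of `spectral_stack`, one per
#'   laser), `miniscope` (matrix), `reference` (confocal vessel-contrast
#'   channel), `masks` (list of `roi_mask` in miniscope coordinates),
#'   `truth` (data.frame `roi_id`, `class`, `amplitude`), `transform`.
#' @export
simulate_image_pair <- function(seed, library,
                                transform = similarity_transform(10, -15, 5, 1.9),
                                confocal_dim = c(160, 160),
                                miniscope_dim = c(96, 96),
                                n_cells = 30, n_vessels = 6,
                                cell_radius = 3, snr = 10, n_z = 2,
                                classes = NULL, render_stacks = TRUE) {
  set.seed(seed)
  nr <- confocal_dim[1]; nc <- confocal_dim[2]
  grid <- library$grid
  A <- sweep(library$matrix, 2, apply(library$matrix, 2, max), "/")
  if (is.null(classes))
    classes <- setdiff(library$labels, "GCaMP6s")

  # dark vessel trees on a bright background, drawn as jittered random walks
  vessel <- matrix(0, nr, nc)
  for (v in seq_len(n_vessels)) {
    y <- runif(1, 1, nr); x <- runif(1, 1, nc)
    th <- runif(1, 0, 2 * pi)
    for (s in seq_len(round(1.5 * max(nr, nc)))) {
      th <- th + rnorm(1, 0, 0.25)
      y <- y + sin(th); x <- x + cos(th)
      if (y < 2 || y > nr - 1 || x < 2 || x > nc - 1) break
      yi <- round(y); xi <- round(x)
      vessel[(yi - 1):(yi + 1), (xi - 1):(xi + 1)] <- 1
    }
  }
  base_scene <- 1 - 0.7 * vessel   # bright field, dark vessels

  # somata: rejection-sample centres to cap overlap
  centers <- matrix(NA_real_, n_cells, 2)
  placed <- 0; tries <- 0
  while (placed < n_cells && tries < 50 * n_cells) {
    tries <- tries + 1
    cand <- c(runif(1, 10, nr - 10), runif(1, 10, nc - 10))
    if (placed == 0 ||
        min(sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE],
                               2, cand)^2))) > 2.5 * cell_radius) {
      placed <- placed + 1
      centers[placed, ] <- cand
    }
  }
  if (placed < n_cells) {
    warning("soma density cap reached; placed ", placed, " of ", n_cells)
    n_cells <- placed
    centers <- centers[seq_len(placed), , drop = FALSE]
  }
  cell_class <- rep_len(classes, n_cells)
  cell_amp <- rlnorm(n_cells, 0, 0.3)

  disk_pixels <- function(cy, cx, r, nrow_, ncol_) {
    ys <- max(1, floor(cy - r)):min(nrow_, ceiling(cy + r))
    xs <- max(1, floor(cx - r)):min(ncol_, ceiling(cx + r))
    g <- expand.grid(y = ys, x = xs)
    g[(g$y - cy)^2 + (g$x - cx)^2 <= r^2, ]
  }

  # confocal spectral stacks: tissue background times the vessel scene,
  # plus each soma's fingerprint, split across z, plus white noise. The
  # background combines a uniform fluorophore mixture with broad
  # violet-excited autofluorescence, which gives the 405 nm / ~512 nm
  # reference channel its vascular contrast (vessels appear as shadows).
  mix <- rowMeans(A)
  af <- flatten_fingerprint(normalize_fingerprint(fingerprint_from_model(
    spectrum_model("autofluorescence", 420, 520, ex_width = 40,
                   em_width = 60), grid), "max_one"))
  bg_spec <- 0.15 * mix + 0.4 * af
  noise_sd <- if (length(cell_amp)) mean(cell_amp) / snr else 0.1 / snr
  stacks <- list()
  for (l in seq_len(if (render_stacks) grid$n_lasers else 0L)) {
    arr <- array(0, dim = c(n_z, grid$n_bins, nr, nc))
    Fl <- matrix(A[((l - 1) * grid$n_bins + 1):(l * grid$n_bins), ],
                 grid$n_bins, ncol(A))
    colnames(Fl) <- colnames(A)
    bgl <- bg_spec[((l - 1) * grid$n_bins + 1):(l * grid$n_bins)]
    for (z in seq_len(n_z)) {
      for (b in seq_len(grid$n_bins)) {
        arr[z, b, , ] <- bgl[b] * base_scene / n_z
      }
    }
    for (ci in seq_len(n_cells)) {
      px <- disk_pixels(centers[ci, 1], centers[ci, 2], cell_radius, nr, nc)
      fvals <- cell_amp[ci] * Fl[, cell_class[ci]] / n_z
      for (z in seq_len(n_z)) for (b in seq_len(grid$n_bins)) {
        if (fvals[b] == 0) next
        idx <- cbind(z, b, px$y, px$x)
        arr[idx] <- arr[idx] + fvals[b]
      }
    }
    arr <- arr + array(rnorm(length(arr), sd = noise_sd / sqrt(n_z) / 10),
                       dim = dim(arr))
    arr[arr < 0] <- 0
    stacks[[as.character(grid$laser_wavelengths[l])]] <-
      spectral_stack(arr, grid$laser_wavelengths[l], pixel_size = 3)
  }

  # confocal vessel-contrast reference: first laser, bin nearest 512 nm
  if (render_stacks) {
    ref_bin <- which.min(abs(bin_centers(grid) - 512))
    reference <- apply(stacks[[1]]$values[, ref_bin, , , drop = FALSE],
                       c(3, 4), sum) + 0.5 * base_scene
  } else {
    reference <- 0.5 * base_scene +
      matrix(rnorm(nr * nc, sd = 0.05 / snr * 10), nr, nc)
  }

  # miniscope view: GCaMP-like intensity scene sampled through the inverse
  # transform (scene lives in confocal coordinates)
  scene <- base_scene
  for (ci in seq_len(n_cells)) {
    px <- disk_pixels(centers[ci, 1], centers[ci, 2], cell_radius, nr, nc)
    scene[cbind(px$y, px$x)] <- scene[cbind(px$y, px$x)] + 0.8 * cell_amp[ci]
  }
  # moving-frame pixel p maps to fixed coords via `transform`; sampling the
  # fixed scene at those coords is warping the scene by the inverse
  mini <- warp_image(scene, miniscope_dim[1], miniscope_dim[2],
                     invert_transform(transform)$tx,
                     invert_transform(transform)$ty,
                     invert_transform(transform)$rotation,
                     invert_transform(transform)$scale, 0L)
  mini[is.na(mini)] <- stats::median(mini, na.rm = TRUE)
  mini <- as.matrix(EBImage::gblur(mini, sigma = 1)) +
    matrix(rnorm(prod(miniscope_dim), sd = 0.02), miniscope_dim[1])

  # ROI masks in miniscope coordinates: map centres through the inverse
  inv <- invert_transform(transform)
  th <- inv$rotation * pi / 180
  cm_f <- (rev(confocal_dim) + 1) / 2    # (cx, cy) fixed
  cm_m <- (rev(miniscope_dim) + 1) / 2
  masks <- list(); truth_rows <- list()
  for (ci in seq_len(n_cells)) {
    u <- centers[ci, 2] - cm_f[1]; v <- centers[ci, 1] - cm_f[2]
    xm <- inv$scale * (cos(th) * u - sin(th) * v) + cm_m[1] + inv$tx
    ym <- inv$scale * (sin(th) * u + cos(th) * v) + cm_m[2] + inv$ty
    r_m <- cell_radius * inv$scale
    if (xm < 1 + r_m || xm > miniscope_dim[2] - r_m ||
        ym < 1 + r_m || ym > miniscope_dim[1] - r_m) next
    px <- disk_pixels(ym, xm, r_m, miniscope_dim[1], miniscope_dim[2])
    id <- sprintf("cell%03d", ci)
    masks[[id]] <- roi_mask(cbind(px$y, px$x), id)
    truth_rows[[id]] <- data.frame(roi_id = id, class = cell_class[ci],
                                   amplitude = cell_amp[ci])
  }
  list(stacks = stacks, miniscope = mini, reference = reference,
       masks = masks, truth = do.call(rbind, truth_rows),
       transform = transform)
}
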