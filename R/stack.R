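#' One-laser spectral z-stack
#'
#' @param values 4-D array indexed (z, bin, y, x), all intensities >= 0.
#' @param laser excitation wavelength (nm).
#' @param pixel_size micrometres per pixel.
#' @param z_step micrometres between z planes.
#' @return a `spectral_stack`.
#' @export
spectral_stack <- function(values, laser, pixel_size = 1, z_step = 5) {
  if (length(dim(values)) != 4)
    stop("stack values must be a 4-D (z, bin, y, x) array", call. = FALSE)
  if (any(values < 0)) stop("stack intensities must be >= 0", call. = FALSE)
  structure(list(values = values, laser = laser,
                 pixel_size = pixel_size, z_step = z_step),
            class = "spectral_stack")
}

# ball structuring element: offsets within radius r and hemisphere heights
ball_kernel <- function(radius_px, height = radius_px) {
  r <- radius_px
  off <- expand.grid(dx = -r:r, dy = -r:r)
  keep <- off$dx^2 + off$dy^2 <= r^2
  off <- off[keep, ]
  h <- sqrt(pmax(r^2 - off$dx^2 - off$dy^2, 0)) * (height / r)
  list(dx = as.integer(off$dx), dy = as.integer(off$dy), h = h)
}

#' Rolling-ball background subtraction
#'
#' Estimates the background of one image plane by grayscale morphological
#' opening with a ball structuring element (erosion then dilation with a
#' hemispheric height profile) and subtracts it, clipping at zero. Used to
#' suppress neuropil and other broad non-somatic signal before z-flattening;
#' the acquisition protocol uses a 30 micrometre ball.
#'
#' @param plane 2-D image matrix.
#' @param radius_um ball radius in micrometres.
#' @param pixel_size micrometres per pixel; the pixel radius is
#'   `round(radius_um / pixel_size)` and must be >= 1.
#' @param ball_height intensity half-height of the ball; defaults to the
#'   pixel radius (a sphere in (x, y, intensity) units).
#' @param shrink for large radii, estimate the background on a block-min
#'   shrunken image with a proportionally smaller ball and enlarge the
#'   estimate bilinearly (the standard acceleration of the rolling-ball
#'   algorithm); exact opening is used when the radius is below 5 px or
#'   `shrink = FALSE`.
#' @return background-subtracted plane, clipped at zero.
#' @export
rolling_ball_subtract <- function(plane, radius_um = 30, pixel_size = 1,
                                  ball_height = NULL, shrink = TRUE) {
  if (radius_um <= 0 || pixel_size <= 0)
    stop("radius_um and pixel_size must be > 0", call. = FALSE)
  r <- round(radius_um / pixel_size)
  if (r < 1) stop("rolling-ball radius is smaller than one pixel", call. = FALSE)
  plane <- as.matrix(plane)
  sf <- if (shrink) max(1L, r %/% 4L) else 1L
  if (sf > 1L) {
    d <- dim(plane)
    nrs <- ceiling(d[1] / sf); ncs <- ceiling(d[2] / sf)
    shrunk <- matrix(Inf, nrs, ncs)
    for (dy in seq_len(sf) - 1L) for (dx in seq_len(sf) - 1L) {
      ri <- pmin((seq_len(nrs) - 1L) * sf + 1L + dy, d[1])
      ci <- pmin((seq_len(ncs) - 1L) * sf + 1L + dx, d[2])
      shrunk <- pmin(shrunk, plane[ri, ci])
    }
    rs <- max(1L, as.integer(round(r / sf)))
    hs <- if (is.null(ball_height)) rs else ball_height / sf
    k <- ball_kernel(rs, hs)
    bg_s <- gray_morph(gray_morph(shrunk, k$dx, k$dy, k$h, 0L),
                       k$dx, k$dy, k$h, 1L)
    bg <- as.matrix(EBImage::resize(bg_s, w = d[1], h = d[2]))
    bg <- pmin(bg, plane)
  } else {
    k <- ball_kernel(r, if (is.null(ball_height)) r else ball_height)
    bg <- gray_morph(gray_morph(plane, k$dx, k$dy, k$h, 0L),
                     k$dx, k$dy, k$h, 1L)
  }
  pmax(plane - bg, 0)
}

#' Flatten a spectral z-stack
#'
#' Applies rolling-ball background subtraction to every (z, bin) plane and
#' sums the retained z planes, removing the wavelength-dependent focal shift
#' introduced by the GRIN lens. The same z-crop must be applied to every
#' laser's stack of one subject.
#'
#' @param stack a `spectral_stack`.
#' @param z_crop `c(first, last)` plane indices to retain (default: all).
#' @param radius_um rolling-ball radius in micrometres; `NULL` skips
#'   background subtraction.
#' @return 3-D array (bin, y, x) of summed, background-subtracted planes.
#' @export
flatten_stack <- function(stack, z_crop = NULL, radius_um = 30) {
  stopifnot(inherits(stack, "spectral_stack"))
  d <- dim(stack$values)
  if (is.null(z_crop)) z_crop <- c(1L, d[1])
  if (z_crop[1] < 1 || z_crop[2] > d[1] || z_crop[1] > z_crop[2])
    stop("z_crop out of bounds or empty", call. = FALSE)
  out <- array(0, dim = d[2:4])
  for (z in z_crop[1]:z_crop[2]) {
    for (b in seq_len(d[2])) {
      plane <- stack$values[z, b, , ]
      if (!is.null(radius_um))
        plane <- rolling_ball_subtract(plane, radius_um, stack$pixel_size)
      out[b, , ] <- out[b, , ] + plane
    }
  }
  out
}

#' ROI mask from pixel coordinates or a logical image
#'
#' @param x either a logical matrix or a two-column matrix/data.frame of
#'   (y, x) pixel coordinates.
#' @param roi_id identifier.
#' @return an `roi_mask` holding integer coordinates.
#' @export
roi_mask <- function(x, roi_id) {
  if (is.logical(x) || (is.matrix(x) && all(x %in% c(0, 1)) && ncol(x) > 2)) {
    idx <- which(x != 0, arr.ind = TRUE)
    coords <- cbind(y = idx[, 1], x = idx[, 2])
  } else {
    coords <- as.matrix(x)
    colnames(coords) <- c("y", "x")
  }
  if (nrow(coords) == 0) stop("ROI mask is empty", call. = FALSE)
  structure(list(coords = coords, roi_id = roi_id), class = "roi_mask")
}

#' Split a label image into ROI masks
#' @param label_image integer matrix; 0 is background, each positive label
#'   one ROI.
#' @return named list of `roi_mask` objects.
#' @export
roi_masks_from_labels <- function(label_image) {
  ids <- sort(setdiff(unique(as.vector(label_image)), 0))
  stats::setNames(lapply(ids, function(i)
    roi_mask(label_image == i, roi_id = as.character(i))),
    as.character(ids))
}

#' Extract a per-ROI spectral fingerprint
#'
#' Averages the flattened spectral images over the pixels of one ROI mask,
#' per laser and emission bin, yielding the ROI's channel fingerprint.
#' Mean (not sum) over pixels, so ROI area does not scale fingerprints.
#'
#' @param flattened_per_laser named list keyed by laser wavelength
#'   (as character, e.g. `"405"`) of 3-D (bin, y, x) arrays from
#'   [flatten_stack()].
#' @param mask an `roi_mask` in the flattened-image coordinate frame.
#' @param grid the `spectral_grid`.
#' @return a `fingerprint` labelled with the ROI id.
#' @export
extract_roi_spectrum <- function(flattened_per_laser, mask, grid) {
  want <- as.character(grid$laser_wavelengths)
  missing <- setdiff(want, names(flattened_per_laser))
  if (length(missing))
    stop("missing flattened stacks for lasers: ",
         paste(missing, collapse = ", "), call. = FALSE)
  vals <- matrix(0, grid$n_lasers, grid$n_bins)
  np <- nrow(mask$coords)
  for (l in seq_along(want)) {
    arr <- flattened_per_laser[[want[l]]]
    d <- dim(arr)
    if (any(mask$coords[, "y"] > d[2]) || any(mask$coords[, "x"] > d[3]) ||
        any(mask$coords < 1))
      stop("ROI mask extends outside the image", call. = FALSE)
    idx <- cbind(rep(seq_len(d[1]), each = np),
                 rep(mask$coords[, "y"], d[1]),
                 rep(mask$coords[, "x"], d[1]))
    vals[l, ] <- colMeans(matrix(arr[idx], np, d[1]))
  }
  vals[vals < 0] <- 0
  fingerprint(vals, mask$roi_id, grid)
}
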