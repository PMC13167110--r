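#' Preprocessing parameters for registration features
#'
#' Vessel-feature extraction before registration: small-sigma Gaussian
#' denoising, large-sigma Gaussian background subtraction, then a
#' morphological black-hat that turns dark vessel-like structures into
#' bright ridges. Defaults follow the acquisition conventions: miniscope
#' images use (1, 50, 11) pixels, confocal reference images (2, 100, 21).
#'
#' @param sigma_denoise denoising Gaussian sigma (px).
#' @param sigma_background background-estimation Gaussian sigma (px);
#'   must exceed `sigma_denoise`.
#' @param blackhat_window odd square window (px) of the black-hat, >= 3.
#' @return a `preprocess_params`.
#' @export
preprocess_params <- function(sigma_denoise = 2, sigma_background = 100,
                              blackhat_window = 21) {
  if (sigma_denoise >= sigma_background)
    stop("sigma_denoise must be < sigma_background", call. = FALSE)
  if (blackhat_window < 3 || blackhat_window %% 2 == 0)
    stop("blackhat_window must be odd and >= 3", call. = FALSE)
  structure(list(sigma_denoise = sigma_denoise,
                 sigma_background = sigma_background,
                 blackhat_window = blackhat_window),
            class = "preprocess_params")
}

#' @rdname preprocess_params
#' @export
miniscope_preprocess_params <- function() preprocess_params(1, 50, 11)

#' @rdname preprocess_params
#' @export
confocal_preprocess_params <- function() preprocess_params(2, 100, 21)

#' Extract registerable vessel features from an image
#'
#' Gaussian denoise, subtract a large-sigma Gaussian-blur background
#' estimate, then black-hat (grayscale closing minus image) with a square
#' window. The output is nonnegative and insensitive to constant intensity
#' offsets of the input.
#'
#' @param image 2-D matrix, finite and non-constant.
#' @param params a `preprocess_params`.
#' @return nonnegative feature image (matrix).
#' @export
preprocess_image <- function(image, params) {
  image <- as.matrix(image)
  if (any(!is.finite(image))) stop("image must be finite", call. = FALSE)
  if (max(image) == min(image))
    stop("constant image has no registerable features", call. = FALSE)
  # kernel radius capped at the image size so large background sigmas work
  # on small fields of view (truncated-Gaussian background estimate)
  blur <- function(img, sigma) {
    radius <- 2 * ceiling(3 * sigma) + 1
    m <- min(dim(img))
    if (radius > m) radius <- m - (1 - m %% 2)
    EBImage::gblur(img, sigma = sigma, radius = radius)
  }
  den <- blur(image, params$sigma_denoise)
  bg <- blur(den, params$sigma_background)
  sub <- den - bg
  brush <- EBImage::makeBrush(params$blackhat_window, shape = "box")
  closed <- EBImage::erode(EBImage::dilate(sub, brush), brush)
  out <- closed - sub
  out[out < 0] <- 0
  as.matrix(out)
}

#' Similarity transform (translation, rotation, global scale)
#'
#' Maps moving-image (miniscope) coordinates into fixed-image (confocal)
#' coordinates: scale about the image centre, rotate about the centre, then
#' translate. `rotation` is in degrees, translations in fixed-image pixels.
#'
#' @param tx,ty translations (px).
#' @param rotation rotation (degrees, counter-clockwise in (x, y)).
#' @param scale global scale (> 0).
#' @return a `similarity_transform`.
#' @export
similarity_transform <- function(tx = 0, ty = 0, rotation = 0, scale = 1) {
  if (scale <= 0) stop("scale must be > 0", call. = FALSE)
  structure(list(tx = tx, ty = ty, rotation = rotation, scale = scale),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("similarity_transform: tx=%.2f ty=%.2f rot=%.2f deg scale=%.4f\n",
              x$tx, x$ty, x$rotation, x$scale))
  invisible(x)
}

#' Invert a similarity transform
#'
#' Exact inverse of the centre-based scale/rotate/translate map for square
#' frames of equal size; composition with the original is the identity to
#' numerical tolerance.
#' @param t a `similarity_transform`.
#' @return the inverse `similarity_transform`.
#' @export
invert_transform <- function(t) {
  th <- -t$rotation * pi / 180
  s <- 1 / t$scale
  # inverse translation expressed in the (scaled, rotated-back) frame
  u <- -t$tx; v <- -t$ty
  similarity_transform(tx = s * (cos(th) * u - sin(th) * v),
                       ty = s * (sin(th) * u + cos(th) * v),
                       rotation = -t$rotation, scale = s)
}

#' Correlation score of a candidate transform
#'
#' Pearson correlation between the fixed image and the moving image warped
#' by `t`, over the valid-overlap region. Zero-mean normalisation makes the
#' score invariant to affine intensity rescaling of either image. Returns
#' `-Inf` when the overlap covers less than `min_overlap` of the fixed
#' image (candidate rejected).
#'
#' @param fixed,moving 2-D matrices (preprocessed feature images).
#' @param t a `similarity_transform`.
#' @param min_overlap minimum overlap fraction of the fixed image.
#' @param stride evaluate every `stride`-th pixel (speed/accuracy knob for
#'   the coarse search).
#' @return correlation in \[-1, 1\], or `-Inf`.
#' @export
correlation_score <- function(fixed, moving, t, min_overlap = 0.25,
                              stride = 1L) {
  warp_correlate(as.matrix(fixed), as.matrix(moving),
                 t$tx, t$ty, t$rotation, t$scale, min_overlap,
                 as.integer(stride))
}

#' Search grid for the coarse registration stage
#'
#' Defaults encode the standard miniscope-to-confocal search space:
#' translations +/- 60 px in steps of 5, rotation +/- 15 degrees in steps
#' of 5, scale 1.8-2.0 in steps of 0.05 (25 x 25 x 7 x 5 = 21,875 nodes).
#' The scale range encodes the pixel-size ratio of the two instruments and
#' should be widened for other setups.
#'
#' @param translation `c(range, step)` in px, searched at
#'   `seq(-range, range, step)` for both axes.
#' @param rotation `c(range, step)` in degrees.
#' @param scale `c(lo, hi, step)`.
#' @param learning_rate step size of the refinement stage.
#' @param coarse_stride pixel stride used when scoring coarse candidates.
#' @return a `search_grid`.
#' @export
search_grid <- function(translation = c(60, 5), rotation = c(15, 5),
                        scale = c(1.8, 2.0, 0.05), learning_rate = 0.5,
                        coarse_stride = 2L) {
  if (translation[2] <= 0 || rotation[2] <= 0 || scale[3] <= 0)
    stop("grid steps must be > 0", call. = FALSE)
  structure(list(
    tx = seq(-translation[1], translation[1], by = translation[2]),
    ty = seq(-translation[1], translation[1], by = translation[2]),
    rot = seq(-rotation[1], rotation[1], by = rotation[2]),
    scale = seq(scale[1], scale[2], by = scale[3]),
    learning_rate = learning_rate,
    coarse_stride = as.integer(coarse_stride)
  ), class = "search_grid")
}

#' Exhaustive coarse registration search
#'
#' Evaluates [correlation_score()] at every grid node and returns the best
#' candidate. Nodes are visited in lexicographic (tx, ty, rotation, scale)
#' order and ties break to the first node visited, so the result is
#' deterministic.
#'
#' @param fixed,moving preprocessed feature images.
#' @param grid a `search_grid`.
#' @param min_overlap minimum overlap fraction.
#' @return list with `transform` (a `similarity_transform`) and `score`.
#' @export
coarse_search <- function(fixed, moving, grid = search_grid(),
                          min_overlap = 0.25) {
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  best <- -Inf
  best_t <- NULL
  for (tx in grid$tx) for (ty in grid$ty)
    for (rot in grid$rot) for (s in grid$scale) {
      sc <- warp_correlate(fixed, moving, tx, ty, rot, s,
                           min_overlap, grid$coarse_stride)
      if (sc > best) {
        best <- sc
        best_t <- similarity_transform(tx, ty, rot, s)
      }
    }
  if (!is.finite(best))
    stop("all coarse candidates rejected for insufficient overlap",
         call. = FALSE)
  list(transform = best_t, score = best)
}

#' Gradient-based refinement of a transform
#'
#' Ascends the correlation objective from `t0` using central finite
#' differences (the resampling objective has no closed-form gradient), with
#' parameter steps of 0.5 px for translations, 0.25 degrees for rotation
#' and 0.005 for scale. The proposal step is backtracked until the score
#' improves, so the returned score is never below `score(t0)`.
#'
#' @param fixed,moving preprocessed feature images.
#' @param t0 starting `similarity_transform` (typically the coarse-search
#'   winner).
#' @param learning_rate step length in normalised parameter units.
#' @param max_iter iteration cap.
#' @param tol stop when the score improvement falls below this.
#' @param steps finite-difference steps `c(tx, ty, rotation, scale)`.
#' @param min_overlap minimum overlap fraction.
#' @return list with `transform`, `score`, `iterations`.
#' @export
refine_transform <- function(fixed, moving, t0, learning_rate = 0.5,
                             max_iter = 200, tol = 1e-6,
                             steps = c(0.5, 0.5, 0.25, 0.005),
                             min_overlap = 0.25) {
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  f <- function(p) warp_correlate(fixed, moving, p[1], p[2], p[3], p[4],
                                  min_overlap, 1L)
  p <- c(t0$tx, t0$ty, t0$rotation, t0$scale)
  cur <- f(p)
  if (!is.finite(cur)) {
    warning("starting transform has no valid overlap; returning it unchanged")
    return(list(transform = t0, score = cur, iterations = 0L))
  }
  it <- 0L
  converged <- FALSE
  while (it < max_iter && !converged) {
    it <- it + 1L
    g <- numeric(4)
    for (i in 1:4) {
      e <- numeric(4); e[i] <- steps[i]
      g[i] <- (f(p + e) - f(p - e)) / 2
    }
    if (any(!is.finite(g))) {
      warning("non-finite gradient during refinement; stopping early")
      break
    }
    gn <- sqrt(sum(g^2))
    if (gn == 0) break
    dir <- g / gn
    lr <- learning_rate
    improved <- FALSE
    while (lr > 1e-4) {
      cand <- p + lr * dir * steps
      val <- f(cand)
      if (is.finite(val) && val > cur) {
        if (val - cur < tol) converged <- TRUE
        p <- cand; cur <- val; improved <- TRUE
        break
      }
      lr <- lr / 2
    }
    if (!improved) break
  }
  list(transform = similarity_transform(p[1], p[2], p[3], p[4]),
       score = cur, iterations = it)
}

#' Apply a similarity transform to an image or ROI mask
#'
#' Warps the target from the moving frame into a fixed frame of size
#' `out_dim`. Images use bilinear interpolation (`NA` outside the source);
#' masks must use nearest-neighbour so labels stay integral.
#'
#' @param target 2-D matrix, or an `roi_mask`.
#' @param t a `similarity_transform`.
#' @param mode `"bilinear"` or `"nearest"`.
#' @param out_dim output (fixed-frame) size `c(rows, cols)`; defaults to
#'   the source size.
#' @param src_dim source (moving-frame) size for `roi_mask` targets, whose
#'   coordinates alone do not determine their frame; defaults to `out_dim`.
#' @return transformed matrix, or an `roi_mask` in fixed coordinates.
#' @export
apply_transform <- function(target, t, mode = c("bilinear", "nearest"),
                            out_dim = NULL, src_dim = NULL) {
  mode <- match.arg(mode)
  if (inherits(target, "roi_mask")) {
    if (is.null(src_dim))
      src_dim <- if (is.null(out_dim))
        c(max(target$coords[, 1]), max(target$coords[, 2])) else out_dim
    if (is.null(out_dim)) out_dim <- src_dim
    img <- matrix(0, src_dim[1], src_dim[2])
    keep <- target$coords[, 1] <= src_dim[1] & target$coords[, 2] <= src_dim[2]
    img[target$coords[keep, , drop = FALSE]] <- 1
    w <- warp_image(img, out_dim[1], out_dim[2],
                    t$tx, t$ty, t$rotation, t$scale, 1L)
    if (!any(w > 0)) stop("transformed ROI mask is empty", call. = FALSE)
    return(roi_mask(w > 0, target$roi_id))
  }
  target <- as.matrix(target)
  if (is.null(out_dim)) out_dim <- dim(target)
  warp_image(target, out_dim[1], out_dim[2],
             t$tx, t$ty, t$rotation, t$scale,
             if (mode == "nearest") 1L else 0L)
}

#' Register a miniscope image to a confocal reference
#'
#' Convenience wrapper: preprocesses both images with their respective
#' parameter presets, runs the coarse exhaustive search, then refines the
#' winner by gradient ascent.
#'
#' @param fixed confocal reference image (vessel-contrast channel).
#' @param moving time-averaged miniscope image.
#' @param grid a `search_grid`.
#' @param fixed_params,moving_params `preprocess_params` for each image.
#' @param min_overlap minimum overlap fraction.
#' @return list with `transform`, `score`, `coarse` (the coarse result) and
#'   the preprocessed images.
#' @export
register_images <- function(fixed, moving, grid = search_grid(),
                            fixed_params = confocal_preprocess_params(),
                            moving_params = miniscope_preprocess_params(),
                            min_overlap = 0.25) {
  pf <- preprocess_image(fixed, fixed_params)
  pm <- preprocess_image(moving, moving_params)
  co <- coarse_search(pf, pm, grid, min_overlap)
  re <- refine_transform(pf, pm, co$transform,
                         learning_rate = grid$learning_rate,
                         min_overlap = min_overlap)
  list(transform = re$transform, score = re$score, coarse = co,
       fixed_features = pf, moving_features = pm)
}

#' Serialize / read a similarity transform
#'
#' Structured-text (YAML) round trip including the score and the coordinate
#' convention tag (scale about centre, then rotation, then translation;
#' moving = miniscope frame, fixed = confocal frame).
#' @param t a `similarity_transform`.
#' @param path output path.
#' @param score optional score stored alongside.
#' @export
write_transform <- function(t, path, score = NA_real_) {
  yaml::write_yaml(list(tx = t$tx, ty = t$ty, rotation_deg = t$rotation,
                        scale = t$scale, score = score,
                        convention = "moving->fixed; scale,rotate about centre, then translate"),
                   path)
  invisible(path)
}

#' @rdname write_transform
#' @return `read_transform` returns a list with `transform` and `score`.
#' @export
read_transform <- function(path) {
  d <- yaml::read_yaml(path)
  list(transform = similarity_transform(d$tx, d$ty, d$rotation_deg, d$scale),
       score = d$score)
}
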