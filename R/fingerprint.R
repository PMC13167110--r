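#' Parametric excitation/emission model of a fluorophore
#'
#' A Gaussian stand-in for an empirically measured spectrum: unit-peak
#' Gaussian excitation and emission curves parameterised by peak and width.
#' The Stokes shift must be non-negative (`em_peak >= ex_peak`).
#'
#' @param name fluorophore label.
#' @param ex_peak,em_peak excitation/emission peak wavelengths (nm).
#' @param ex_width,em_width Gaussian sigma of the curves (nm).
#' @param brightness relative brightness scalar (>= 0).
#' @return a `spectrum_model`.
#' @export
spectrum_model <- function(name, ex_peak, em_peak,
                           ex_width = 18, em_width = 22, brightness = 1) {
  if (em_peak < ex_peak) stop("em_peak must be >= ex_peak", call. = FALSE)
  if (ex_width <= 0 || em_width <= 0) stop("widths must be > 0", call. = FALSE)
  if (brightness < 0) stop("brightness must be >= 0", call. = FALSE)
  structure(list(name = name, ex_peak = ex_peak, em_peak = em_peak,
                 ex_width = ex_width, em_width = em_width,
                 brightness = brightness), class = "spectrum_model")
}

#' Default fluorophore peak table
#'
#' Approximate published excitation/emission peaks for the nine projection
#' labels plus the GCaMP6s calcium indicator. These parametric models stand
#' in for empirically recorded reference fingerprints while preserving the
#' relative spectral separability of the set.
#'
#' @return named list of `spectrum_model` objects.
#' @export
default_spectrum_models <- function() {
  tab <- list(
    c(399, 454), c(434, 474), c(399, 511), c(497, 515), c(515, 528),
    c(549, 565), c(528, 594), c(569, 594), c(580, 608), c(599, 643))
  names(tab) <- c("mTagBFP2", "mTurquoise2", "T-Sapphire", "GCaMP6s",
                  "mVenus", "mOrange2", "mCyRFP1", "mScarlet",
                  "FusionRed", "mNeptune2.5")
  lapply(names(tab), function(nm)
    spectrum_model(nm, tab[[nm]][1], tab[[nm]][2])) |>
    stats::setNames(names(tab))
}

#' Construct a fingerprint from raw values
#' @param values nonnegative matrix indexed (laser, bin).
#' @param label fluorophore or ROI identifier.
#' @param grid the `spectral_grid` the values live on.
#' @return a `fingerprint`.
#' @export
fingerprint <- function(values, label, grid) {
  values <- as.matrix(values)
  if (nrow(values) != grid$n_lasers || ncol(values) != grid$n_bins)
    stop("fingerprint shape does not match grid", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("fingerprint values must be finite and >= 0", call. = FALSE)
  dimnames(values) <- list(paste0("ex", grid$laser_wavelengths), NULL)
  structure(list(values = values, label = label, grid = grid),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("fingerprint '%s': %d x %d channels, max %.4g\n",
              x$label, nrow(x$values), ncol(x$values), max(x$values)))
  invisible(x)
}

# integral of a unit-peak Gaussian over [lo, hi]
gauss_band_integral <- function(peak, width, lo, hi) {
  width * sqrt(2 * pi) *
    (pnorm((hi - peak) / width) - pnorm((lo - peak) / width))
}

#' Sample a spectrum model onto the measurement grid
#'
#' Computes `entry(l, b) = brightness * power_l * T(lambda_l) * Ex(lambda_l)
#' * integral of Em over bin b`, where Ex and Em are the model's unit-peak
#' Gaussian curves. Bins overlapping the +/- `guard_nm` band around an
#' excitation line are zeroed for that laser, emulating beam-splitter
#' rejection of scattered laser light.
#'
#' @param model a `spectrum_model`.
#' @param grid a `spectral_grid`.
#' @param laser_powers per-laser power scalars (recycled if length 1).
#' @param transmission optional function of wavelength (nm) giving relative
#'   transmission, e.g. built from [fit_transmission()]; defaults to 1.
#' @param guard_nm half-width of the laser-line blocking band.
#' @return a `fingerprint`.
#' @examples
#' g <- build_grid()
#' f <- fingerprint_from_model(spectrum_model("x", 490, 520), g)
#' @export
fingerprint_from_model <- function(model, grid, laser_powers = 1,
                                   transmission = NULL, guard_nm = 10) {
  stopifnot(inherits(model, "spectrum_model"), inherits(grid, "spectral_grid"))
  powers <- rep_len(laser_powers, grid$n_lasers)
  if (any(powers < 0)) stop("laser powers must be >= 0", call. = FALSE)
  tfun <- if (is.null(transmission)) function(w) rep(1, length(w)) else transmission
  lo <- grid$bin_edges[-length(grid$bin_edges)]
  hi <- grid$bin_edges[-1]
  em <- gauss_band_integral(model$em_peak, model$em_width, lo, hi)
  vals <- matrix(0, grid$n_lasers, grid$n_bins)
  for (l in seq_len(grid$n_lasers)) {
    wl <- grid$laser_wavelengths[l]
    ex <- exp(-(wl - model$ex_peak)^2 / (2 * model$ex_width^2))
    row <- model$brightness * powers[l] * tfun(wl) * ex * em
    if (guard_nm > 0) {
      blocked <- hi > wl - guard_nm & lo < wl + guard_nm
      row[blocked] <- 0
    }
    vals[l, ] <- row
  }
  fingerprint(vals, model$name, grid)
}

#' Normalize a fingerprint
#'
#' @param f a `fingerprint`.
#' @param mode `"max_one"` divides by the maximum entry (the normalisation
#'   used for the beta_norm unmixing channel); `"unit_sum"` divides by the
#'   total.
#' @return a normalized `fingerprint`.
#' @export
normalize_fingerprint <- function(f, mode = c("max_one", "unit_sum")) {
  mode <- match.arg(mode)
  s <- if (mode == "max_one") max(f$values) else sum(f$values)
  if (s <= 0) stop("cannot normalize an all-zero fingerprint", call. = FALSE)
  fingerprint(f$values / s, f$label, f$grid)
}

#' Flatten a fingerprint to a channel vector
#'
#' Laser-major order (all bins of laser 1, then laser 2, ...), matching
#' [channel_names()].
#' @param f a `fingerprint`.
#' @return numeric vector of length `n_lasers * n_bins`.
#' @export
flatten_fingerprint <- function(f) as.vector(t(f$values))

#' Build a reference fingerprint library
#'
#' Samples each spectrum model onto the grid and assembles the channel x
#' fluorophore reference matrix used for unmixing. Each reference is
#' max-one normalized by default, so that simulated ROI amplitudes are
#' expressed in units of peak channel intensity. Linear independence is
#' checked numerically and the condition number of the flattened matrix is
#' stored in `$condition_number`.
#'
#' @param models list of `spectrum_model` objects (default
#'   [default_spectrum_models()]).
#' @param grid a `spectral_grid`.
#' @param laser_powers,transmission,guard_nm passed to
#'   [fingerprint_from_model()].
#' @param normalize normalisation applied to each reference
#'   (`"max_one"` or `"none"`).
#' @return a `reference_library` with fields `fingerprints`, `matrix`
#'   (channels x fluorophores), `labels`, `grid`, `condition_number`.
#' @export
build_reference_library <- function(models = default_spectrum_models(),
                                    grid = build_grid(),
                                    laser_powers = 1, transmission = NULL,
                                    guard_nm = 10,
                                    normalize = c("max_one", "none")) {
  normalize <- match.arg(normalize)
  fps <- lapply(models, function(m) {
    f <- fingerprint_from_model(m, grid, laser_powers, transmission, guard_nm)
    if (normalize == "max_one") f <- normalize_fingerprint(f, "max_one")
    f
  })
  reference_library(fps, grid)
}

#' Assemble a reference library from fingerprints
#' @param fingerprints list of `fingerprint` objects sharing one grid.
#' @param grid the shared `spectral_grid`.
#' @return a `reference_library`.
#' @export
reference_library <- function(fingerprints, grid) {
  labels <- vapply(fingerprints, function(f) f$label, character(1))
  A <- vapply(fingerprints, flatten_fingerprint,
              numeric(grid$n_lasers * grid$n_bins))
  colnames(A) <- labels
  sv <- svd(A, nu = 0, nv = 0)$d
  if (min(sv) <= max(sv) * 1e-10)
    stop("reference fingerprints are numerically rank deficient", call. = FALSE)
  structure(list(fingerprints = stats::setNames(fingerprints, labels),
                 matrix = A, labels = labels, grid = grid,
                 condition_number = max(sv) / min(sv)),
            class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("reference_library: %d fluorophores on %d channels (cond %.1f)\n",
              length(x$labels), nrow(x$matrix), x$condition_number))
  cat(" ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Subset a reference library
#' @param library a `reference_library`.
#' @param labels fluorophore labels to keep (order preserved as given).
#' @return a `reference_library` restricted to `labels`.
#' @export
subset_library <- function(library, labels) {
  miss <- setdiff(labels, library$labels)
  if (length(miss)) stop("unknown fluorophores: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  reference_library(library$fingerprints[labels], library$grid)
}

#' Write fingerprints to a delimited table
#'
#' Long format with columns `label, laser_nm, bin_lo_nm, bin_hi_nm, value`,
#' one row per channel per fingerprint.
#' @param x a `reference_library` or list of `fingerprint` objects.
#' @param path output TSV path.
#' @export
write_fingerprints <- function(x, path) {
  fps <- if (inherits(x, "reference_library")) x$fingerprints else x
  grid <- fps[[1]]$grid
  lo <- grid$bin_edges[-length(grid$bin_edges)]
  hi <- grid$bin_edges[-1]
  rows <- do.call(rbind, lapply(fps, function(f) {
    data.frame(label = f$label,
               laser_nm = rep(grid$laser_wavelengths, each = grid$n_bins),
               bin_lo_nm = rep(lo, grid$n_lasers),
               bin_hi_nm = rep(hi, grid$n_lasers),
               value = as.vector(t(f$values)))
  }))
  write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read fingerprints written by [write_fingerprints()]
#' @param path TSV path.
#' @return a `reference_library`.
#' @export
read_fingerprints <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  need <- c("label", "laser_nm", "bin_lo_nm", "bin_hi_nm", "value")
  if (!all(need %in% names(d)))
    stop("fingerprint table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lasers <- sort(unique(d$laser_nm))
  edges <- sort(unique(c(d$bin_lo_nm, d$bin_hi_nm)))
  n_bins <- length(edges) - 1L
  grid <- structure(list(laser_wavelengths = lasers, bin_edges = edges,
                         n_lasers = length(lasers), n_bins = n_bins),
                    class = "spectral_grid")
  fps <- lapply(split(d, factor(d$label, levels = unique(d$label))), function(s) {
    s <- s[order(match(s$laser_nm, lasers), s$bin_lo_nm), ]
    fingerprint(matrix(s$value, grid$n_lasers, n_bins, byrow = TRUE),
                s$label[1], grid)
  })
  reference_library(fps, grid)
}
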