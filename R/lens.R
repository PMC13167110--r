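#' Polynomial calibration fits for GRIN-lens optics
#'
#' Least-squares polynomial fit used for the axial chromatic-shift and
#' transmission calibrations. Coefficients are stored lowest degree first;
#' `r_squared` is `1 - SS_res / SS_tot` on the fitted points.
#'
#' @param x,y calibration points (wavelength nm, value).
#' @param degree polynomial degree.
#' @return a `poly_fit` with `coefficients`, `degree`, `r_squared`, `domain`.
#' @keywords internal
fit_polynomial <- function(x, y, degree) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < degree + 1)
    stop(sprintf("need at least %d points for a degree-%d fit",
                 degree + 1, degree), call. = FALSE)
  fit <- lm(y ~ poly(x, degree, raw = TRUE))
  cf <- unname(coef(fit))
  cf[is.na(cf)] <- 0
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(coefficients = cf, degree = degree,
                 r_squared = r2, domain = range(x)),
            class = "poly_fit")
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf("poly_fit degree %d, R^2 = %.4f, domain %g-%g nm\n",
              x$degree, x$r_squared, x$domain[1], x$domain[2]))
  invisible(x)
}

#' Evaluate a polynomial fit
#'
#' @param fit a `poly_fit`.
#' @param x wavelengths (nm); values outside the fitted domain trigger an
#'   extrapolation warning.
#' @param clip optional `c(lo, hi)` interval the prediction is clipped to
#'   (transmission fits are clipped to `(0, 1]` on evaluation).
#' @return numeric predictions.
#' @export
eval_polyfit <- function(fit, x, clip = NULL) {
  stopifnot(inherits(fit, "poly_fit"))
  if (any(x < fit$domain[1] | x > fit$domain[2]))
    warning("evaluating polynomial fit outside its fitted domain (extrapolation)")
  y <- drop(outer(x, 0:fit$degree, `^`) %*% fit$coefficients)
  if (!is.null(clip)) y <- pmin(pmax(y, clip[1]), clip[2])
  y
}

#' Fit the axial chromatic focal shift
#'
#' The GRIN lens shifts the focal plane downward at longer wavelengths; the
#' wavelength vs z-focal-plane relationship is well described by a
#' second-order polynomial. The fit is informational (acquisition planning):
#' the computational correction for the shift is the summed z-projection in
#' [flatten_stack()].
#'
#' @param wavelengths excitation wavelengths (nm), >= 3 points.
#' @param focal_z focal-plane positions (micrometres).
#' @return a `poly_fit` of degree 2.
#' @export
fit_axial_shift <- function(wavelengths, focal_z) {
  fit_polynomial(wavelengths, focal_z, degree = 2)
}

#' Fit wavelength-dependent GRIN transmission
#'
#' Transmission through the lens peaks between 550 and 600 nm and falls
#' steeply in the violet; a sixth-order polynomial captures the measured
#' curve. Evaluate with [eval_polyfit()] using `clip = c(1e-6, 1)`, or let
#' [plan_powers()] handle it.
#'
#' @param wavelengths calibration wavelengths (nm), at least `degree + 1`.
#' @param transmission transmitted fraction in (0, 1].
#' @param degree polynomial degree (default 6).
#' @return a `poly_fit`.
#' @export
fit_transmission <- function(wavelengths, transmission, degree = 6) {
  if (any(transmission <= 0 | transmission > 1))
    stop("transmission values must be in (0, 1]", call. = FALSE)
  fit_polynomial(wavelengths, transmission, degree = degree)
}

#' Transmission function from a fit
#' @param fit a transmission `poly_fit`.
#' @return a function of wavelength returning clipped transmission, usable
#'   as the `transmission` argument of [fingerprint_from_model()].
#' @export
transmission_function <- function(fit) {
  function(w) eval_polyfit(fit, w, clip = c(1e-6, 1))
}

#' Plan per-laser excitation powers from a transmission fit
#'
#' The brightest laser serves as the reference; every other laser's power is
#' multiplied by `T(reference) / T(laser)` so that the illumination reaching
#' the sample is uniform across wavelengths. Lasers listed in `overrides`
#' bypass the correction and carry an absolute power fraction instead (the
#' red line exciting only the far-red fluorophore is conventionally fixed,
#' e.g. `overrides = c("639" = 0.40)`).
#'
#' @param fit transmission `poly_fit` valid over all lasers.
#' @param reference_laser reference wavelength (nm).
#' @param lasers laser wavelengths to plan (nm).
#' @param overrides named numeric vector, laser nm -> absolute power fraction.
#' @return a `power_plan` with `multipliers` (named per laser),
#'   `fixed_overrides`, and `reference_laser`.
#' @export
plan_powers <- function(fit, reference_laser, lasers, overrides = numeric()) {
  tvals <- eval_polyfit(fit, c(reference_laser, lasers))
  if (any(tvals <= 0))
    stop("fitted transmission is <= 0 at a planned laser", call. = FALSE)
  t_ref <- tvals[1]
  mult <- t_ref / tvals[-1]
  names(mult) <- as.character(lasers)
  ov <- names(overrides)
  fixed <- stats::setNames(as.numeric(overrides), ov)
  mult[ov[ov %in% names(mult)]] <- NA_real_
  structure(list(reference_laser = reference_laser, multipliers = mult,
                 fixed_overrides = fixed), class = "power_plan")
}

#' @export
print.power_plan <- function(x, ...) {
  cat(sprintf("power_plan (reference %g nm)\n", x$reference_laser))
  for (nm in names(x$multipliers)) {
    if (nm %in% names(x$fixed_overrides))
      cat(sprintf("  %s nm: fixed at %.0f%% power\n",
                  nm, 100 * x$fixed_overrides[[nm]]))
    else
      cat(sprintf("  %s nm: x%.3f\n", nm, x$multipliers[[nm]]))
  }
  invisible(x)
}

#' Read calibration points from a delimited table
#' @param path TSV/CSV with columns `wavelength_nm` and `value`.
#' @return data.frame with those columns.
#' @export
read_calibration <- function(path) {
  d <- read.delim(path, sep = "", check.names = FALSE)
  if (!all(c("wavelength_nm", "value") %in% names(d)))
    stop("calibration table needs columns wavelength_nm, value", call. = FALSE)
  d
}
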