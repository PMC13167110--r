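#' Build the spectral measurement grid
#'
#' Defines the laser x emission-bin measurement space used throughout the
#' package. The default grid matches the multiplexed acquisition scheme:
#' six excitation lasers (405, 488, 514, 561, 594, 639 nm) and 34 emission
#' bins, of which the first spans 350-400 nm, the last 695-750 nm, and 32
#' uniform interior bins partition 400-695 nm, giving 204 channels in all.
#'
#' @param laser_wavelengths excitation laser lines in nm.
#' @param interior_span nm interval partitioned by the uniform interior bins.
#' @param n_interior number of interior bins.
#' @param outer_span nm limits of the first and last (wide) bins.
#' @return a `spectral_grid` object with fields `laser_wavelengths`,
#'   `bin_edges` (length `n_bins + 1`), `n_lasers`, `n_bins`.
#' @examples
#' g <- build_grid()
#' g$n_lasers * g$n_bins  # 204
#' @export
build_grid <- function(laser_wavelengths = c(405, 488, 514, 561, 594, 639),
                       interior_span = c(400, 695),
                       n_interior = 32,
                       outer_span = c(350, 750)) {
  if (length(laser_wavelengths) < 1 || any(!is.finite(laser_wavelengths)))
    stop("laser_wavelengths must be finite nm values", call. = FALSE)
  if (n_interior < 1 || diff(interior_span) <= 0)
    stop("invalid interior bin configuration", call. = FALSE)
  edges <- c(outer_span[1],
             seq(interior_span[1], interior_span[2], length.out = n_interior + 1),
             outer_span[2])
  if (any(diff(edges) <= 0))
    stop("bin edges must be strictly increasing", call. = FALSE)
  g <- structure(list(
    laser_wavelengths = as.numeric(laser_wavelengths),
    bin_edges = edges,
    n_lasers = length(laser_wavelengths),
    n_bins = length(edges) - 1L
  ), class = "spectral_grid")
  g
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("spectral_grid: %d lasers x %d bins = %d channels\n",
              x$n_lasers, x$n_bins, x$n_lasers * x$n_bins))
  cat("  lasers (nm):", paste(x$laser_wavelengths, collapse = ", "), "\n")
  cat(sprintf("  bins: %.0f-%.0f nm (interior width %.2f nm)\n",
              min(x$bin_edges), max(x$bin_edges), x$bin_edges[3] - x$bin_edges[2]))
  invisible(x)
}

#' Bin centres of a spectral grid
#' @param grid a `spectral_grid`.
#' @return numeric vector of emission-bin centre wavelengths (nm).
#' @export
bin_centers <- function(grid) {
  (grid$bin_edges[-1] + grid$bin_edges[-length(grid$bin_edges)]) / 2
}

#' Channel labels for a flattened fingerprint
#'
#' Flattening is laser-major: all bins of the first laser, then all bins of
#' the second, and so on.
#' @param grid a `spectral_grid`.
#' @return character vector of length `n_lasers * n_bins`.
#' @export
channel_names <- function(grid) {
  ctr <- bin_centers(grid)
  as.vector(t(outer(grid$laser_wavelengths, ctr,
                    function(l, b) sprintf("ex%g_em%.1f", l, b))))
}
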