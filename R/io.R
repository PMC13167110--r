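#' Write a spectral stack as a multi-page TIFF
#'
#' Pages are ordered z-major then bin (all bins of z-plane 1, then z-plane
#' 2, ...), matching the declared page-order convention of the run config.
#' Values are stored as 32-bit float scaled to the unit interval; the intensity scale
#' is kept in a plain-text sidecar (`<path>.scale`) and restored on read.
#'
#' @param stack a `spectral_stack`.
#' @param path output TIFF path.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack$values)
  scale <- max(stack$values)
  if (scale <= 0) scale <- 1
  pages <- vector("list", d[1] * d[2])
  i <- 0L
  for (z in seq_len(d[1])) for (b in seq_len(d[2])) {
    i <- i + 1L
    pages[[i]] <- stack$values[z, b, , ] / scale
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  writeLines(sprintf("%.17g", scale), paste0(path, ".scale"))
  invisible(path)
}

#' Read a spectral stack written by [write_stack_tiff()]
#' @param path TIFF path.
#' @param n_z,n_bins page layout (z-major then bin).
#' @param laser,pixel_size,z_step stack metadata.
#' @return a `spectral_stack`.
#' @export
read_stack_tiff <- function(path, n_z, n_bins, laser, pixel_size = 1,
                            z_step = 5) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != n_z * n_bins)
    stop(sprintf("expected %d pages, found %d", n_z * n_bins, length(pages)),
         call. = FALSE)
  scale_file <- paste0(path, ".scale")
  scale <- if (file.exists(scale_file))
    as.numeric(readLines(scale_file, n = 1)) else 1
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(n_z, n_bins, d[1], d[2]))
  i <- 0L
  for (z in seq_len(n_z)) for (b in seq_len(n_bins)) {
    i <- i + 1L
    arr[z, b, , ] <- pages[[i]] * scale
  }
  spectral_stack(arr, laser, pixel_size, z_step)
}

#' Write / read a 2-D image as TIFF
#'
#' Stored as 32-bit float scaled into the unit interval; the affine intensity scale
#' and offset live in a plain-text sidecar (`<path>.scale`) and are
#' restored on read.
#' @param image matrix.
#' @param path TIFF path.
#' @export
write_image_tiff <- function(image, path) {
  m <- as.matrix(image)
  lo <- min(m)
  span <- max(m) - lo
  if (span <= 0) span <- 1
  tiff::writeTIFF((m - lo) / span, path, bits.per.sample = 32)
  writeLines(sprintf("%.17g %.17g", span, lo), paste0(path, ".scale"))
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  scale_file <- paste0(path, ".scale")
  if (file.exists(scale_file)) {
    sc <- as.numeric(strsplit(readLines(scale_file, n = 1), " ")[[1]])
    m <- m * sc[1] + sc[2]
  }
  m
}

#' Write ROI masks as coordinate tables
#' @param masks list of `roi_mask`.
#' @param path TSV path (columns `roi_id`, `y`, `x`).
#' @export
write_roi_masks <- function(masks, path) {
  rows <- do.call(rbind, lapply(masks, function(m)
    data.frame(roi_id = m$roi_id, y = m$coords[, "y"], x = m$coords[, "x"])))
  write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_roi_masks
#' @export
read_roi_masks <- function(path) {
  d <- read.delim(path)
  lapply(split(d, factor(d$roi_id, levels = unique(d$roi_id))),
         function(s) roi_mask(cbind(s$y, s$x), as.character(s$roi_id[1])))
}

#' Write ROI spectra as a wide table
#' @param spectra channels x ROIs matrix (column names = ROI ids).
#' @param grid the `spectral_grid` (channel order must match
#'   [channel_names()]).
#' @param path TSV path.
#' @export
write_spectra <- function(spectra, grid, path) {
  d <- data.frame(channel = channel_names(grid), spectra,
                  check.names = FALSE)
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  m <- as.matrix(d[setdiff(names(d), "channel")])
  rownames(m) <- d$channel
  m
}
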