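#' Peri-event behavioral selectivity of one cell
#'
#' For each behavior onset, the mean calcium activity in the window before
#' onset is compared with the mean in the window after; a two-sided t-test
#' across epochs (paired by default) decides whether the cell modulates its
#' activity around that behavior. Events whose pre or post window falls
#' outside the trace are dropped and counted.
#'
#' @param trace numeric ΔF/F vector sampled at `fs` Hz.
#' @param onsets behavior onset times in seconds (sorted, nonnegative).
#' @param fs sampling rate (Hz).
#' @param window window length in seconds on each side of the onset
#'   (default 2.5 s).
#' @param alpha uncorrected significance level.
#' @param n_behaviors Bonferroni divisor: the number of behaviors tested
#'   for this cell/session.
#' @param paired paired t-test across epochs (default); `FALSE` uses
#'   Welch's unpaired test on the epoch means.
#' @return a `selectivity_result`: `t`, `p`, `selective`
#'   (`p < alpha / n_behaviors`), `corrected_alpha`, `n_epochs`,
#'   `n_dropped`, `testable`.
#' @export
peri_event_selectivity <- function(trace, onsets, fs = 20, window = 2.5,
                                   alpha = 0.05, n_behaviors = 1,
                                   paired = TRUE) {
  if (fs <= 0 || window <= 0) stop("fs and window must be > 0", call. = FALSE)
  if (is.unsorted(onsets)) onsets <- sort(onsets)
  n_side <- round(window * fs)
  n <- length(trace)
  pre <- post <- numeric(0)
  dropped <- 0L
  for (t0 in onsets) {
    i0 <- floor(t0 * fs) + 1L      # first sample at/after onset
    if (i0 - n_side < 1 || i0 + n_side - 1 > n) { dropped <- dropped + 1L; next }
    pre <- c(pre, mean(trace[(i0 - n_side):(i0 - 1L)]))
    post <- c(post, mean(trace[i0:(i0 + n_side - 1L)]))
  }
  m <- length(pre)
  corrected <- alpha / n_behaviors
  if (m < 2) {
    return(structure(list(t = NA_real_, p = NA_real_, selective = FALSE,
                          corrected_alpha = corrected, n_epochs = m,
                          n_dropped = dropped, testable = FALSE),
                     class = "selectivity_result"))
  }
  d <- post - pre
  if (paired && sd(d) == 0) {
    # constant paired differences: degenerate t (0 or +/- infinity)
    tt <- if (mean(d) == 0) list(statistic = c(t = 0), p.value = 1)
          else list(statistic = c(t = sign(mean(d)) * Inf), p.value = 0)
  } else if (!paired && sd(post) == 0 && sd(pre) == 0) {
    tt <- if (mean(d) == 0) list(statistic = c(t = 0), p.value = 1)
          else list(statistic = c(t = sign(mean(d)) * Inf), p.value = 0)
  } else {
    tt <- t.test(post, pre, paired = paired)
  }
  structure(list(t = unname(tt$statistic), p = tt$p.value,
                 selective = is.finite(tt$p.value) && tt$p.value < corrected,
                 corrected_alpha = corrected, n_epochs = m,
                 n_dropped = dropped, testable = TRUE),
            class = "selectivity_result")
}

#' Selectivity table for many cells and behaviors
#'
#' Runs [peri_event_selectivity()] for every cell x behavior combination,
#' Bonferroni-correcting within each cell by the number of behaviors.
#'
#' @param traces numeric matrix (time x cells) with cell ids as column
#'   names, or a data.frame with a `time` column plus one column per cell.
#' @param events data.frame with columns `behavior`, `onset_s`.
#' @param fs,window,alpha,paired as in [peri_event_selectivity()].
#' @return data.frame with one row per cell x behavior: `cell`, `behavior`,
#'   `t`, `p`, `selective`, `n_epochs`, `n_dropped`.
#' @export
selectivity_table <- function(traces, events, fs = 20, window = 2.5,
                              alpha = 0.05, paired = TRUE) {
  if (is.data.frame(traces) && "time" %in% names(traces))
    traces <- as.matrix(traces[setdiff(names(traces), "time")])
  traces <- as.matrix(traces)
  if (is.null(colnames(traces)))
    colnames(traces) <- paste0("cell", seq_len(ncol(traces)))
  behaviors <- unique(events$behavior)
  m <- length(behaviors)
  rows <- list()
  for (cell in colnames(traces)) for (b in behaviors) {
    r <- peri_event_selectivity(traces[, cell],
                                events$onset_s[events$behavior == b],
                                fs = fs, window = window, alpha = alpha,
                                n_behaviors = m, paired = paired)
    rows[[length(rows) + 1L]] <- data.frame(
      cell = cell, behavior = b, t = r$t, p = r$p, selective = r$selective,
      n_epochs = r$n_epochs, n_dropped = r$n_dropped)
  }
  do.call(rbind, rows)
}

#' Tabulate behavioral selectivity by assigned identity
#'
#' Counts, per cell, the number of behaviors for which it is selective, and
#' aggregates the counts by the cell's primary fluorophore identity.
#' Cells without an assignment are grouped as `"no match"`.
#'
#' @param results data.frame from [selectivity_table()].
#' @param identities a `classification`, list of `assignment_result`s, or
#'   data.frame with `roi_id` and `primary` columns; cell ids must match.
#' @return list with `per_cell` (cell, identity, n_selective) and
#'   `by_identity` (identity, table of behavior counts).
#' @export
selectivity_counts <- function(results, identities) {
  if (inherits(identities, "classification") || is.list(identities) &&
      !is.data.frame(identities)) {
    res <- if (inherits(identities, "classification"))
      identities$assignments else identities
    identities <- data.frame(
      roi_id = vapply(res, function(a) as.character(a$roi_id), character(1)),
      primary = vapply(res, function(a) a$primary, character(1)))
  }
  if (anyDuplicated(identities$roi_id))
    stop("duplicate cell ids in identities", call. = FALSE)
  counts <- tapply(results$selective, results$cell, sum)
  per_cell <- data.frame(cell = names(counts),
                         n_selective = as.integer(counts))
  idmap <- stats::setNames(identities$primary, identities$roi_id)
  per_cell$identity <- idmap[per_cell$cell]
  per_cell$identity[is.na(per_cell$identity)] <- "no match"
  by_identity <- tapply(per_cell$n_selective, per_cell$identity,
                        function(x) table(factor(x, levels = 0:max(per_cell$n_selective))))
  list(per_cell = per_cell, by_identity = by_identity)
}
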