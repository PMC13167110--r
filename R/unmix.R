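# Lawson-Hanson non-negative least squares on the Gram matrix.
# The reference library has ~10 columns, so working with the k x k normal
# equations (precomputed once per library) makes the ~10^5 per-ROI fits of
# the simulation engine cheap.
nnls_gram <- function(G, Atb, max_iter = 10 * length(Atb)) {
  k <- length(Atb)
  x <- numeric(k)
  P <- logical(k)
  w <- Atb                      # gradient of the objective at x = 0
  iter <- 0
  tol <- 1e-10 * max(1, max(abs(Atb)))
  while (any(!P) && any(w[!P] > tol) && iter < max_iter) {
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      iter <- iter + 1
      s <- numeric(k)
      s[P] <- solve(G[P, P, drop = FALSE], Atb[P])
      if (all(s[P] > 0)) { x <- s; break }
      neg <- P & s <= 0
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
      if (iter >= max_iter) break
    }
    w <- Atb - G %*% x
  }
  pmax(x, 0)
}

# Precompute the pieces of the raw and max-normalized unmixing problems.
unmix_context <- function(library, nonneg = TRUE) {
  A <- library$matrix
  An <- sweep(A, 2, apply(A, 2, max), "/")
  list(A = A, An = An,
       G = crossprod(A), Gn = crossprod(An),
       nonneg = nonneg, labels = library$labels)
}

solve_betas <- function(ctx, y, normalized = FALSE) {
  A <- if (normalized) ctx$An else ctx$A
  G <- if (normalized) ctx$Gn else ctx$G
  if (ctx$nonneg) nnls_gram(G, drop(crossprod(A, y)))
  else drop(solve(G, crossprod(A, y)))
}

#' Fit per-fluorophore beta multipliers for one ROI spectrum
#'
#' Linear unmixing: finds the nonnegative multiplier (beta) of each
#' reference fingerprint whose weighted sum best reconstructs the measured
#' spectrum, in the least-squares sense. Two channels are fit: `beta_raw`
#' on the raw spectrum, and `beta_norm` on the max-one-normalized spectrum
#' against max-one-normalized references. The two channels have
#' complementary biases for bright and dim ROIs, and either can trigger a
#' hit downstream.
#'
#' @param spectrum a `fingerprint` (ROI spectrum) on the library's grid.
#' @param library a `reference_library`.
#' @param nonneg constrain betas to be nonnegative (default); set `FALSE`
#'   for an unconstrained ordinary least-squares fit.
#' @return a `beta_vector` with `beta_raw`, `beta_norm` (named per
#'   fluorophore), `residual` (raw-channel residual norm) and `roi_id`.
#' @export
fit_betas <- function(spectrum, library, nonneg = TRUE) {
  if (!identical(dim(spectrum$values),
                 c(library$grid$n_lasers, library$grid$n_bins)))
    stop("spectrum and library are on different grids", call. = FALSE)
  ctx <- unmix_context(library, nonneg)
  y <- flatten_fingerprint(spectrum)
  out <- fit_betas_one(ctx, y, spectrum$label)
  out
}

fit_betas_one <- function(ctx, y, roi_id) {
  k <- length(ctx$labels)
  if (max(y) <= 0) {
    br <- bn <- stats::setNames(numeric(k), ctx$labels)
    return(structure(list(beta_raw = br, beta_norm = bn, residual = 0,
                          roi_id = roi_id), class = "beta_vector"))
  }
  br <- solve_betas(ctx, y, normalized = FALSE)
  bn <- solve_betas(ctx, y / max(y), normalized = TRUE)
  res <- sqrt(sum((y - ctx$A %*% br)^2))
  structure(list(beta_raw = stats::setNames(drop(br), ctx$labels),
                 beta_norm = stats::setNames(drop(bn), ctx$labels),
                 residual = res, roi_id = roi_id),
            class = "beta_vector")
}

#' Fit betas for a collection of ROI spectra
#'
#' Vectorised front end to [fit_betas()]: precomputes the library Gram
#' matrices once and fits every ROI.
#'
#' @param spectra list of `fingerprint` objects, or a channels x ROIs
#'   matrix with ROI ids as column names.
#' @param library a `reference_library`.
#' @param nonneg as in [fit_betas()].
#' @return list of `beta_vector` objects.
#' @export
fit_betas_all <- function(spectra, library, nonneg = TRUE) {
  ctx <- unmix_context(library, nonneg)
  if (is.list(spectra)) {
    ids <- vapply(spectra, function(f) as.character(f$label), character(1))
    Y <- vapply(spectra, flatten_fingerprint, numeric(nrow(library$matrix)))
  } else {
    Y <- as.matrix(spectra)
    ids <- colnames(Y)
    if (is.null(ids)) ids <- as.character(seq_len(ncol(Y)))
  }
  lapply(seq_len(ncol(Y)), function(i) fit_betas_one(ctx, Y[, i], ids[i]))
}

beta_matrix <- function(betas, channel = c("raw", "norm")) {
  channel <- match.arg(channel)
  field <- if (channel == "raw") "beta_raw" else "beta_norm"
  vapply(betas, function(b) b[[field]], numeric(length(betas[[1]]$beta_raw)))
}

#' Per-subject baseline statistics of beta values
#'
#' The spectral baseline: per-fluorophore mean and population SD of
#' `beta_raw` and `beta_norm` over all ROIs of one subject, and the hit
#' cutoffs `mean + k * SD` (k = 1.5 by default). Computing the baseline per
#' subject absorbs animal-to-animal differences in background signal and
#' expression level.
#'
#' @param betas list of `beta_vector` objects for all ROIs of one subject
#'   (at least 2).
#' @param k SD multiplier of the cutoff.
#' @return a `baseline_stats` with `mean_raw`, `sd_raw`, `cutoff_raw`,
#'   `mean_norm`, `sd_norm`, `cutoff_norm` (named per fluorophore) and `k`.
#' @export
compute_baseline <- function(betas, k = 1.5) {
  if (length(betas) < 2)
    stop("baseline needs at least 2 ROIs (SD undefined)", call. = FALSE)
  R <- beta_matrix(betas, "raw")
  N <- beta_matrix(betas, "norm")
  pop_sd <- function(m) sqrt(pmax(rowMeans(m^2) - rowMeans(m)^2, 0))
  mr <- rowMeans(R); mn <- rowMeans(N)
  sr <- pop_sd(R); sn <- pop_sd(N)
  structure(list(mean_raw = mr, sd_raw = sr, cutoff_raw = mr + k * sr,
                 mean_norm = mn, sd_norm = sn, cutoff_norm = mn + k * sn,
                 k = k, n_rois = length(betas)),
            class = "baseline_stats")
}

beta_zscores <- function(beta, baseline) {
  z <- function(b, m, s) ifelse(s > 0, (b - m) / s, 0)
  list(raw = z(beta$beta_raw, baseline$mean_raw, baseline$sd_raw),
       norm = z(beta$beta_norm, baseline$mean_norm, baseline$sd_norm))
}

assign_with_cutoffs <- function(beta, baseline, cutoff_raw, cutoff_norm,
                                pass_id, candidates = NULL) {
  zs <- beta_zscores(beta, baseline)
  zmax <- pmax(zs$raw, zs$norm)
  hits <- which(beta$beta_raw > cutoff_raw | beta$beta_norm > cutoff_norm)
  if (!is.null(candidates))
    hits <- hits[names(beta$beta_raw)[hits] %in% candidates]
  if (length(hits)) {
    ord <- hits[order(zmax[hits], decreasing = TRUE)]
    primary <- names(beta$beta_raw)[ord[1]]
    secondaries <- names(beta$beta_raw)[ord[-1]]
  } else {
    primary <- NA_character_
    secondaries <- character()
  }
  structure(list(roi_id = beta$roi_id,
                 hits = names(beta$beta_raw)[hits],
                 primary = primary, secondaries = secondaries,
                 pass_id = pass_id,
                 z_raw = zs$raw, z_norm = zs$norm),
            class = "assignment_result")
}

#' Single-pass fluorophore assignment for one ROI
#'
#' A fluorophore is a hit when its `beta_raw` exceeds the raw cutoff or its
#' `beta_norm` exceeds the normalized cutoff. Among hits, the fluorophore
#' with the largest z-scored beta (max of the raw and normalized z) becomes
#' the primary identity (winner-take-all); remaining hits are retained as
#' secondaries in decreasing z order.
#'
#' @param beta a `beta_vector`.
#' @param baseline a `baseline_stats` from the same subject's ROIs.
#' @param candidates labels eligible as identities (default: every library
#'   member). The calcium indicator stays in the unmixing library so its
#'   background is absorbed by its own beta, but is excluded from the
#'   candidate set when it is not an identity of interest.
#' @return an `assignment_result` with `pass_id = 1`.
#' @export
single_pass_assign <- function(beta, baseline, candidates = NULL) {
  assign_with_cutoffs(beta, baseline, baseline$cutoff_raw,
                      baseline$cutoff_norm, pass_id = 1L,
                      candidates = candidates)
}

#' Beta share profile
#'
#' Each fluorophore's summed beta as a percent of the total over a set of
#' ROIs; used to compare the subject's measured fluorophore distribution
#' with the theoretical equal distribution in the dual-pass adjustment.
#'
#' @param betas list of `beta_vector` objects.
#' @param channel `"raw"` or `"norm"`.
#' @param source label stored with the profile.
#' @return a `share_profile`: named percentages summing to 100.
#' @export
share_profile <- function(betas, channel = "raw", source = "experimental") {
  M <- beta_matrix(betas, channel)
  tot <- rowSums(M)
  if (sum(tot) <= 0) stop("all betas are zero; shares undefined", call. = FALSE)
  structure(list(shares = 100 * tot / sum(tot), source = source),
            class = "share_profile")
}

#' Theoretical equal-distribution share profile
#'
#' Shares obtained by unmixing one pure, unit-amplitude copy of every
#' reference fingerprint — the beta contribution each fluorophore would
#' carry in a perfectly balanced dataset.
#'
#' @param library a `reference_library`.
#' @param nonneg as in [fit_betas()].
#' @return a `share_profile` with `source = "theoretical_equal"`.
#' @export
theoretical_shares <- function(library, nonneg = TRUE) {
  ctx <- unmix_context(library, nonneg)
  betas <- lapply(seq_along(library$labels), function(i)
    fit_betas_one(ctx, library$matrix[, i], library$labels[i]))
  share_profile(betas, "raw", source = "theoretical_equal")
}

#' Dual-pass re-assignment of unassigned ROIs
#'
#' Second classification pass for ROIs that produced no hit in pass 1.
#' For each fluorophore the over-representation ratio (experimental share
#' divided by theoretical share) is computed; when the ratio exceeds 1 the
#' cutoff is lowered to mean + k * SD / ratio (the SD term shrinks in
#' proportion to over-representation), otherwise it is unchanged. The
#' single-pass rule is then re-run with the adjusted cutoffs on the
#' unassigned ROIs only.
#'
#' @param unassigned list of `beta_vector` objects with no pass-1 hits.
#' @param baseline the subject's `baseline_stats`.
#' @param theoretical a `share_profile` from [theoretical_shares()].
#' @param experimental the subject's `share_profile` over all ROIs.
#' @param candidates as in [single_pass_assign()].
#' @return list of `assignment_result` objects with `pass_id = 2`.
#' @export
dual_pass_assign <- function(unassigned, baseline, theoretical, experimental,
                             candidates = NULL) {
  th <- theoretical$shares
  ex <- experimental$shares
  if (any(th <= 0))
    stop("theoretical share is zero for some fluorophore", call. = FALSE)
  r <- pmax(ex / th, 1)
  cutoff_raw <- baseline$mean_raw + baseline$k * baseline$sd_raw / r
  cutoff_norm <- baseline$mean_norm + baseline$k * baseline$sd_norm / r
  lapply(unassigned, function(b)
    assign_with_cutoffs(b, baseline, cutoff_raw, cutoff_norm, pass_id = 2L,
                        candidates = candidates))
}

#' Classify all ROIs of one subject
#'
#' Full per-subject pipeline: fit raw and normalized betas for every ROI,
#' compute the baseline cutoffs, assign identities in pass 1, and (when
#' `dual_pass = TRUE`) re-evaluate the pass-1 no-hit ROIs with
#' over-representation-adjusted cutoffs in pass 2. Deterministic given its
#' inputs; permuting ROI order permutes the results identically.
#'
#' @param spectra list of ROI `fingerprint`s, or a channels x ROIs matrix
#'   (>= 2 ROIs).
#' @param library a `reference_library`.
#' @param k SD multiplier for the cutoffs.
#' @param dual_pass enable the second pass.
#' @param candidates labels eligible as identities (default: all library
#'   members); see [single_pass_assign()].
#' @param nonneg as in [fit_betas()].
#' @return a `classification` list: `assignments` (one `assignment_result`
#'   per ROI, input order), `betas`, `baseline`, `experimental_shares`,
#'   `theoretical_shares`.
#' @export
classify_subject <- function(spectra, library, k = 1.5, dual_pass = TRUE,
                             candidates = NULL, nonneg = TRUE) {
  n <- if (is.list(spectra)) length(spectra) else ncol(spectra)
  if (n < 2) stop("classification needs at least 2 ROIs", call. = FALSE)
  betas <- fit_betas_all(spectra, library, nonneg)
  baseline <- compute_baseline(betas, k)
  res <- lapply(betas, single_pass_assign, baseline = baseline,
                candidates = candidates)
  exp_shares <- share_profile(betas, "raw", "experimental")
  theo <- theoretical_shares(library, nonneg)
  if (dual_pass) {
    miss <- which(vapply(res, function(a) length(a$hits) == 0, logical(1)))
    if (length(miss)) {
      res2 <- dual_pass_assign(betas[miss], baseline, theo, exp_shares,
                               candidates = candidates)
      res[miss] <- res2
    }
  }
  structure(list(assignments = res, betas = betas, baseline = baseline,
                 experimental_shares = exp_shares, theoretical_shares = theo,
                 k = k, dual_pass = dual_pass, candidates = candidates),
            class = "classification")
}

#' Tabulate assignment results
#'
#' @param x a `classification` or list of `assignment_result`s.
#' @return data.frame with `roi_id`, `pass`, `primary`, `secondaries`
#'   (comma-separated), `n_hits`, and per-fluorophore z columns.
#' @export
assignments_table <- function(x) {
  res <- if (inherits(x, "classification")) x$assignments else x
  base <- data.frame(
    roi_id = vapply(res, function(a) as.character(a$roi_id), character(1)),
    pass = vapply(res, function(a) a$pass_id, integer(1)),
    primary = vapply(res, function(a) a$primary, character(1)),
    secondaries = vapply(res, function(a)
      paste(a$secondaries, collapse = ","), character(1)),
    n_hits = vapply(res, function(a) length(a$hits), integer(1)),
    stringsAsFactors = FALSE)
  zr <- t(vapply(res, function(a) a$z_raw, res[[1]]$z_raw))
  zn <- t(vapply(res, function(a) a$z_norm, res[[1]]$z_norm))
  colnames(zr) <- paste0("z_raw.", colnames(zr))
  colnames(zn) <- paste0("z_norm.", colnames(zn))
  cbind(base, zr, zn)
}
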