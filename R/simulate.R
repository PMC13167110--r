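#' Simulation configuration for synthetic ROI datasets
#'
#' Describes one simulated dataset of ROI spectra: which fluorophore
#' classes occur and at what frequency, amplitude heterogeneity, calcium-
#' indicator (GCaMP) background, uniform spectral background, additive
#' white noise, and optional dual labelling.
#'
#' Amplitudes are log-normal in units of peak channel intensity
#' (references are max-one normalized when composing spectra). SNR is
#' defined as the mean peak spectral amplitude divided by the noise SD.
#'
#' @param class_distribution named per-fluorophore fractions summing to 1;
#'   names must be library labels.
#' @param n_rois ROIs per dataset.
#' @param gcamp_fraction ratio g of GCaMP amplitude to the mean fluorophore
#'   amplitude, added to every ROI.
#' @param background_fraction ratio b of background amplitude to the mean
#'   fluorophore amplitude (mode `"uniform"`), or to the ROI's own
#'   amplitude (mode `"second_fluorophore"`).
#' @param background_mode `"uniform"` adds an equal mixture of all
#'   non-GCaMP fluorophore spectra; `"second_fluorophore"` adds one
#'   randomly chosen different fluorophore's spectrum per ROI.
#' @param snr mean peak signal over noise SD; `Inf` disables noise.
#' @param dual_label every ROI carries two distinct fluorophores (summed
#'   pure spectra) when `TRUE`.
#' @param replicates replicate count used by [run_sweep()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param amplitude_meanlog,amplitude_sdlog log-normal amplitude
#'   parameters.
#' @param gcamp_label library label of the calcium indicator.
#' @return a `simulation_config`.
#' @export
simulation_config <- function(class_distribution, n_rois = 460,
                              gcamp_fraction = 0, background_fraction = 0,
                              background_mode = c("uniform",
                                                  "second_fluorophore"),
                              snr = Inf, dual_label = FALSE,
                              replicates = 100, seed = NULL,
                              amplitude_meanlog = 0, amplitude_sdlog = 0.5,
                              gcamp_label = "GCaMP6s") {
  background_mode <- match.arg(background_mode)
  p <- class_distribution
  if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("class_distribution must be named, nonnegative, and sum to 1",
         call. = FALSE)
  if (n_rois < 1 || snr <= 0)
    stop("n_rois must be >= 1 and snr > 0", call. = FALSE)
  structure(list(class_distribution = p, n_rois = as.integer(n_rois),
                 gcamp_fraction = gcamp_fraction,
                 background_fraction = background_fraction,
                 background_mode = background_mode, snr = snr,
                 dual_label = dual_label, replicates = as.integer(replicates),
                 seed = seed, amplitude_meanlog = amplitude_meanlog,
                 amplitude_sdlog = amplitude_sdlog,
                 gcamp_label = gcamp_label),
            class = "simulation_config")
}

#' Equal class distribution over a label set
#' @param labels fluorophore labels.
#' @return named fractions, each `1 / length(labels)`.
#' @export
equal_distribution <- function(labels) {
  stats::setNames(rep(1 / length(labels), length(labels)), labels)
}

#' Empirical-like class distribution over the nine projection labels
#'
#' A fixed non-uniform distribution emulating the detection-frequency
#' pattern seen in projection-labelled cortex: the bright yellow-green
#' labels most frequent, the dim red labels least. Used by
#' [realistic_config()].
#' @return named fractions summing to 1.
#' @export
realistic_distribution <- function() {
  c(mVenus = 0.20, "T-Sapphire" = 0.18, mOrange2 = 0.13, mScarlet = 0.12,
    mNeptune2.5 = 0.10, mTagBFP2 = 0.09, mTurquoise2 = 0.08,
    mCyRFP1 = 0.05, FusionRed = 0.05)
}

#' Realistic-condition simulation preset
#'
#' Encodes the in-vivo-like stress condition: empirical-like class
#' distribution across the nine injected fluorophores, GCaMP background at
#' 30% of mean fluorophore amplitude, uniform spectral background at 30%,
#' and white noise at SNR 6.
#'
#' @param class_distribution named fractions (default
#'   [realistic_distribution()]).
#' @param ... overrides passed to [simulation_config()].
#' @return a `simulation_config`.
#' @export
realistic_config <- function(class_distribution = realistic_distribution(),
                             ...) {
  args <- list(class_distribution = class_distribution,
               gcamp_fraction = 0.30, background_fraction = 0.30,
               snr = 6)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

#' Simulate a dataset of ROI spectra with ground truth
#'
#' For each ROI a class is drawn from the configured distribution and a
#' log-normal amplitude assigned; the spectrum is the amplitude-scaled
#' reference plus (optionally) GCaMP background, uniform or
#' second-fluorophore spectral background, and white noise with
#' SD = mean amplitude / SNR, clipped at zero. Dual-label mode sums two
#' independently drawn pure spectra before the perturbations. Fully
#' reproducible from the config seed.
#'
#' @param config a `simulation_config`.
#' @param library a `reference_library`; must contain the GCaMP label when
#'   `gcamp_fraction > 0`.
#' @return list with `spectra` (channels x ROIs matrix, ROI ids as column
#'   names) and `truth` (data.frame `roi_id`, `class`, `class2`,
#'   `amplitude`, `amplitude2`, `contaminant`, `dual`).
#' @export
simulate_roi_dataset <- function(config, library) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(library, "reference_library"))
  p <- config$class_distribution
  miss <- setdiff(names(p), library$labels)
  if (length(miss))
    stop("classes not in library: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (config$gcamp_fraction > 0 && !(config$gcamp_label %in% library$labels))
    stop("library lacks '", config$gcamp_label,
         "' but gcamp_fraction > 0", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)

  A <- sweep(library$matrix, 2, apply(library$matrix, 2, max), "/")
  n <- config$n_rois
  cls <- sample(names(p), n, replace = TRUE, prob = p)
  amp <- rlnorm(n, config$amplitude_meanlog, config$amplitude_sdlog)
  cls2 <- rep(NA_character_, n)
  amp2 <- rep(NA_real_, n)
  contaminant <- rep(NA_character_, n)

  S <- A[, cls, drop = FALSE] %*% diag(amp, n)
  if (config$dual_label) {
    cls2 <- vapply(cls, function(c1) {
      q <- p[names(p) != c1]
      sample(names(q), 1, prob = q)
    }, character(1))
    amp2 <- rlnorm(n, config$amplitude_meanlog, config$amplitude_sdlog)
    S <- S + A[, cls2, drop = FALSE] %*% diag(amp2, n)
  }
  abar <- mean(if (config$dual_label) c(amp, amp2) else amp)
  if (config$gcamp_fraction > 0)
    S <- S + config$gcamp_fraction * abar *
      matrix(A[, config$gcamp_label], nrow(A), n)
  if (config$background_fraction > 0) {
    if (config$background_mode == "uniform") {
      mix_labels <- setdiff(colnames(A), config$gcamp_label)
      mix <- rowMeans(A[, mix_labels, drop = FALSE])
      S <- S + config$background_fraction * abar * matrix(mix, nrow(A), n)
    } else {
      contaminant <- vapply(cls, function(c1)
        sample(setdiff(colnames(A), c(c1, config$gcamp_label)), 1),
        character(1))
      S <- S + A[, contaminant, drop = FALSE] %*%
        diag(config$background_fraction * amp, n)
    }
  }
  if (is.finite(config$snr)) {
    S <- S + matrix(rnorm(length(S), sd = abar / config$snr), nrow(S))
    S[S < 0] <- 0
  }
  ids <- sprintf("roi%04d", seq_len(n))
  colnames(S) <- ids
  list(spectra = S,
       truth = data.frame(roi_id = ids, class = cls, class2 = cls2,
                          amplitude = amp, amplitude2 = amp2,
                          contaminant = contaminant,
                          dual = config$dual_label,
                          stringsAsFactors = FALSE))
}

#' Score assignments against ground truth
#'
#' Single-label ROIs: correct when the primary equals the true class,
#' false negative when no fluorophore was assigned, false positive when a
#' wrong fluorophore was assigned (the three fractions sum to 1).
#' Dual-label ROIs: `at_least_one` when the hit set intersects the true
#' pair, `both` when it contains the pair, `secondary_fp` when it contains
#' a fluorophore outside the pair.
#'
#' @param results a `classification` or list of `assignment_result`s in
#'   the same ROI order as `truth`.
#' @param truth the `truth` data.frame from [simulate_roi_dataset()].
#' @return a `sim_metrics` list with `single` (accuracy,
#'   false_negative_rate, false_positive_rate, n), `per_fluorophore`
#'   (accuracy/fn/fp by true class) and, for dual data, `dual`
#'   (at_least_one, both, secondary_fp, n).
#' @export
evaluate_assignments <- function(results, truth) {
  res <- if (inherits(results, "classification")) results$assignments
         else results
  ids <- vapply(res, function(a) as.character(a$roi_id), character(1))
  if (!identical(ids, as.character(truth$roi_id)))
    stop("ROI ids of results and truth do not match", call. = FALSE)
  primary <- vapply(res, function(a) a$primary, character(1))
  hit_sets <- lapply(res, function(a) a$hits)
  is_dual <- !is.na(truth$class2)

  out <- list()
  if (any(!is_dual)) {
    tc <- truth$class[!is_dual]
    pr <- primary[!is_dual]
    correct <- !is.na(pr) & pr == tc
    fn <- is.na(pr)
    fp <- !is.na(pr) & pr != tc
    out$single <- c(accuracy = mean(correct), false_negative_rate = mean(fn),
                    false_positive_rate = mean(fp), n = sum(!is_dual))
    out$per_fluorophore <- do.call(rbind, lapply(unique(tc), function(f) {
      i <- tc == f
      data.frame(fluorophore = f, n = sum(i), accuracy = mean(correct[i]),
                 false_negative_rate = mean(fn[i]),
                 false_positive_rate = mean(fp[i]))
    }))
  }
  if (any(is_dual)) {
    pair <- cbind(truth$class[is_dual], truth$class2[is_dual])
    hs <- hit_sets[is_dual]
    alo <- vapply(seq_len(nrow(pair)), function(i)
      length(intersect(hs[[i]], pair[i, ])) >= 1, logical(1))
    both <- vapply(seq_len(nrow(pair)), function(i)
      all(pair[i, ] %in% hs[[i]]), logical(1))
    sfp <- vapply(seq_len(nrow(pair)), function(i)
      length(setdiff(hs[[i]], pair[i, ])) > 0, logical(1))
    out$dual <- c(at_least_one = mean(alo), both = mean(both),
                  secondary_fp = mean(sfp), n = nrow(pair))
  }
  structure(out, class = "sim_metrics")
}

#' Monte-Carlo sweep over a perturbation axis
#'
#' Runs simulate -> classify -> evaluate for every value of one
#' perturbation axis, replicated with derived seeds, and aggregates the
#' single-label metrics.
#'
#' @param base a `simulation_config`; its seed seeds the sweep.
#' @param axis `"gcamp"`, `"background"`, `"snr"` or `"prevalence"`.
#' @param values axis values. For `"prevalence"`, the fraction of the
#'   population given to `dominant`; the remaining classes share the rest
#'   in proportion to their base fractions.
#' @param library a `reference_library`.
#' @param dominant fluorophore label used by the prevalence axis (default:
#'   first class).
#' @param dual_pass,k,candidates classifier options (see
#'   [classify_subject()]).
#' @param replicates overrides `base$replicates`.
#' @return data.frame with one row per value x replicate: overall
#'   `accuracy`, `false_negative_rate`, `false_positive_rate`, and
#'   `dominant_accuracy` (accuracy among the dominant fluorophore's ROIs;
#'   `NA` off the prevalence axis).
#' @export
run_sweep <- function(base, axis = c("gcamp", "background", "snr",
                                     "prevalence"),
                      values, library, dominant = NULL, dual_pass = TRUE,
                      k = 1.5, candidates = NULL, replicates = NULL) {
  axis <- match.arg(axis)
  if (is.null(replicates)) replicates <- base$replicates
  if (is.null(dominant)) dominant <- names(base$class_distribution)[1]
  seed0 <- if (is.null(base$seed)) 1L else base$seed
  rows <- list()
  for (vi in seq_along(values)) {
    v <- values[vi]
    for (rep_i in seq_len(replicates)) {
      cfg <- base
      cfg$seed <- (seed0 + 7919L * (vi - 1L) + rep_i) %% .Machine$integer.max
      if (axis == "gcamp") cfg$gcamp_fraction <- v
      if (axis == "background") cfg$background_fraction <- v
      if (axis == "snr") cfg$snr <- v
      if (axis == "prevalence") {
        p <- base$class_distribution
        others <- p[names(p) != dominant]
        cfg$class_distribution <-
          c(stats::setNames(v, dominant), others / sum(others) * (1 - v))
      }
      sim <- simulate_roi_dataset(cfg, library)
      cl <- classify_subject(sim$spectra, library, k = k,
                             dual_pass = dual_pass, candidates = candidates)
      m <- evaluate_assignments(cl, sim$truth)
      pf <- m$per_fluorophore
      dom_acc <- if (dominant %in% pf$fluorophore)
        pf$accuracy[pf$fluorophore == dominant] else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        axis = axis, value = v, replicate = rep_i,
        accuracy = m$single[["accuracy"]],
        false_negative_rate = m$single[["false_negative_rate"]],
        false_positive_rate = m$single[["false_positive_rate"]],
        dominant_accuracy = dom_acc)
    }
  }
  do.call(rbind, rows)
}

#' Summarise a sweep table
#' @param sweep data.frame from [run_sweep()].
#' @return data.frame of mean and SD per axis value.
#' @export
summarize_sweep <- function(sweep) {
  vals <- unique(sweep$value)
  do.call(rbind, lapply(vals, function(v) {
    s <- sweep[sweep$value == v, ]
    data.frame(value = v,
               accuracy_mean = mean(s$accuracy),
               accuracy_sd = sd(s$accuracy),
               fn_mean = mean(s$false_negative_rate),
               fp_mean = mean(s$false_positive_rate),
               dominant_accuracy_mean = mean(s$dominant_accuracy))
  }))
}
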