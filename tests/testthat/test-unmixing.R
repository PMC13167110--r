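test_that("pure reference spectra unmix to a unit beta", {
  for (lab in c("mTagBFP2", "mVenus", "mNeptune2.5")) {
    b <- fit_betas(default_lib$fingerprints[[lab]], default_lib)
    expect_equal(unname(b$beta_raw[lab]), 1, tolerance = 1e-9)
    expect_lt(max(b$beta_raw[names(b$beta_raw) != lab]), 1e-9)
    expect_lt(b$residual, 1e-9)
  }
})

test_that("noiseless two-component mixtures are recovered exactly", {
  g <- default_lib$grid
  y <- 0.7 * default_lib$matrix[, "mVenus"] +
       0.3 * default_lib$matrix[, "mScarlet"]
  f <- fingerprint(matrix(y, g$n_lasers, g$n_bins, byrow = TRUE), "mix", g)
  b <- fit_betas(f, default_lib)
  # oracle: unconstrained normal-equations solve (all-nonnegative optimum)
  oracle <- solve(crossprod(default_lib$matrix),
                  crossprod(default_lib$matrix, y))
  expect_equal(unname(b$beta_raw), unname(pmax(drop(oracle), 0)),
               tolerance = 1e-6)
  expect_equal(unname(b$beta_raw["mVenus"]), 0.7, tolerance = 1e-6)
  expect_equal(unname(b$beta_raw["mScarlet"]), 0.3, tolerance = 1e-6)
})

test_that("degenerate inputs are handled by contract", {
  g <- default_lib$grid
  zero <- fingerprint(matrix(0, g$n_lasers, g$n_bins), "z", g)
  b <- fit_betas(zero, default_lib)
  expect_true(all(b$beta_raw == 0))
  expect_equal(b$residual, 0)
  small <- fingerprint(matrix(1, 2, 34), "x", build_grid(c(405, 488)))
  expect_error(fit_betas(small, default_lib), "grids")
})

test_that("nonnegative solver agrees with an independent active-set oracle", {
  set.seed(99)
  A <- default_lib$matrix
  for (i in 1:50) {
    coef <- runif(10) * (runif(10) < 0.5)
    y <- drop(A %*% coef) + rnorm(204, sd = 0.02)
    y[y < 0] <- 0
    ours <- fit_betas_all(matrix(y, ncol = 1), default_lib)[[1]]$beta_raw
    oracle <- pracma::lsqnonneg(A, y)$x
    expect_equal(unname(ours), oracle, tolerance = 1e-6)
  }
})

test_that("unconstrained mode reproduces ordinary least squares", {
  set.seed(5)
  y <- drop(default_lib$matrix %*% runif(10)) + rnorm(204, sd = 0.05)
  b <- fit_betas_all(matrix(abs(y), ncol = 1), default_lib,
                     nonneg = FALSE)[[1]]
  ols <- solve(crossprod(default_lib$matrix),
               crossprod(default_lib$matrix, abs(y)))
  expect_equal(unname(b$beta_raw), unname(drop(ols)), tolerance = 1e-8)
})

test_that("baseline statistics implement the mean + k*SD cutoff", {
  # fluorophore with mean 0.10 and SD 0.02 must cut off at 0.13
  vals <- c(0.08, 0.10, 0.12)       # population SD = 0.0163
  vals <- 0.10 + (vals - mean(vals)) / sqrt(mean((vals - mean(vals))^2)) * 0.02
  betas <- lapply(seq_along(vals), function(i)
    make_beta(c(f1 = vals[i], f2 = 0.5), roi_id = i))
  bl <- compute_baseline(betas, k = 1.5)
  expect_equal(unname(bl$mean_raw["f1"]), 0.10, tolerance = 1e-12)
  expect_equal(unname(bl$cutoff_raw["f1"]), 0.13, tolerance = 1e-12)
  # identical betas: SD collapses and the cutoff equals the mean
  same <- lapply(1:4, function(i) make_beta(c(f1 = 0.2, f2 = 0.1)))
  bl2 <- compute_baseline(same)
  expect_equal(unname(bl2$sd_raw), c(0, 0))
  expect_equal(bl2$cutoff_raw, bl2$mean_raw)
  expect_error(compute_baseline(same[1]), "at least 2")
})

test_that("baseline mean and SD match the direct formula oracle", {
  set.seed(21)
  M <- matrix(abs(rnorm(5 * 40)), 5, 40,
              dimnames = list(paste0("f", 1:5), NULL))
  betas <- lapply(1:40, function(i) make_beta(M[, i], roi_id = i))
  bl <- compute_baseline(betas)
  for (f in rownames(M)) {
    expect_equal(unname(bl$mean_raw[f]), mean(M[f, ]), tolerance = 1e-12)
    expect_equal(unname(bl$sd_raw[f]),
                 sqrt(mean((M[f, ] - mean(M[f, ]))^2)), tolerance = 1e-12)
  }
})

test_that("single-pass assignment follows the hit and winner-take-all rules", {
  bl <- structure(list(
    mean_raw = c(a = 0.10, b = 0.10, c = 0.10),
    sd_raw = c(a = 0.02, b = 0.02, c = 0.02),
    cutoff_raw = c(a = 0.13, b = 0.13, c = 0.13),
    mean_norm = c(a = 0.10, b = 0.10, c = 0.10),
    sd_norm = c(a = 0.02, b = 0.02, c = 0.02),
    cutoff_norm = c(a = 0.13, b = 0.13, c = 0.13),
    k = 1.5, n_rois = 10), class = "baseline_stats")
  # 0.15 against a 0.13 cutoff is a hit
  r1 <- single_pass_assign(make_beta(c(a = 0.15, b = 0.10, c = 0.10)), bl)
  expect_equal(r1$hits, "a")
  expect_equal(r1$primary, "a")
  expect_equal(r1$pass_id, 1L)
  # two hits: z-scores 4.2 (a) and 2.1 (b) rank a as primary
  r2 <- single_pass_assign(
    make_beta(c(a = 0.10 + 4.2 * 0.02, b = 0.10 + 2.1 * 0.02, c = 0.10)), bl)
  expect_equal(r2$primary, "a")
  expect_equal(r2$secondaries, "b")
  # betas at the baseline mean produce no hits
  r3 <- single_pass_assign(make_beta(c(a = 0.10, b = 0.10, c = 0.10)), bl)
  expect_length(r3$hits, 0)
  expect_true(is.na(r3$primary))
  # the OR rule: a norm-channel exceedance alone triggers the hit
  r4 <- single_pass_assign(make_beta(c(a = 0.1, b = 0.1, c = 0.1),
                                     norm = c(a = 0.1, b = 0.2, c = 0.1)), bl)
  expect_equal(r4$hits, "b")
  # candidate restriction excludes non-candidate hits
  r5 <- single_pass_assign(make_beta(c(a = 0.2, b = 0.2, c = 0.1)), bl,
                           candidates = c("b", "c"))
  expect_equal(r5$primary, "b")
  expect_false("a" %in% r5$hits)
})

test_that("dual-pass adjustment lowers cutoffs for over-represented fluorophores", {
  bl <- structure(list(
    mean_raw = c(a = 0.10, b = 0.10), sd_raw = c(a = 0.02, b = 0.02),
    cutoff_raw = c(a = 0.13, b = 0.13),
    mean_norm = c(a = 0.10, b = 0.10), sd_norm = c(a = 0.02, b = 0.02),
    cutoff_norm = c(a = 0.13, b = 0.13),
    k = 1.5, n_rois = 10), class = "baseline_stats")
  theo <- structure(list(shares = c(a = 10, b = 90),
                         source = "theoretical_equal"),
                    class = "share_profile")
  expr <- structure(list(shares = c(a = 40, b = 60), source = "experimental"),
                    class = "share_profile")
  # a: ratio 4 shrinks the SD term to 0.02/4 -> cutoff 0.1075
  hit <- dual_pass_assign(list(make_beta(c(a = 0.11, b = 0.0))),
                          bl, theo, expr)[[1]]
  expect_equal(hit$hits, "a")
  expect_equal(hit$pass_id, 2L)
  miss <- dual_pass_assign(list(make_beta(c(a = 0.105, b = 0.0))),
                           bl, theo, expr)[[1]]
  expect_length(miss$hits, 0)
  # b: ratio below 1 leaves the cutoff at 0.13
  b_miss <- dual_pass_assign(list(make_beta(c(a = 0, b = 0.125))),
                             bl, theo, expr)[[1]]
  expect_length(b_miss$hits, 0)
  bad_theo <- structure(list(shares = c(a = 0, b = 100), source = "t"),
                        class = "share_profile")
  expect_error(dual_pass_assign(list(make_beta(c(a = 1, b = 0))),
                                bl, bad_theo, expr), "theoretical")
})

test_that("theoretical shares of the default library are near-equal", {
  th <- theoretical_shares(default_lib)
  expect_equal(sum(th$shares), 100, tolerance = 1e-9)
  expect_true(all(abs(th$shares - 10) < 0.5))
})

test_that("noiseless equal mixes classify perfectly in pass 1", {
  cfg <- simulation_config(equal_distribution(default_lib$labels),
                           n_rois = 200, snr = Inf, seed = 41)
  sim <- simulate_roi_dataset(cfg, default_lib)
  cl <- classify_subject(sim$spectra, default_lib)
  primary <- vapply(cl$assignments, function(a) a$primary, character(1))
  pass <- vapply(cl$assignments, function(a) a$pass_id, integer(1))
  expect_equal(primary, sim$truth$class, ignore_attr = TRUE)
  expect_true(all(pass == 1L))
  expect_error(classify_subject(sim$spectra[, 1, drop = FALSE], default_lib),
               "at least 2")
})

test_that("classification is equivariant under ROI permutation", {
  cfg <- simulation_config(equal_distribution(default_lib$labels),
                           n_rois = 60, snr = 8, seed = 42)
  sim <- simulate_roi_dataset(cfg, default_lib)
  cl1 <- classify_subject(sim$spectra, default_lib)
  perm <- sample(60)
  cl2 <- classify_subject(sim$spectra[, perm], default_lib)
  p1 <- vapply(cl1$assignments, function(a) a$primary, character(1))
  p2 <- vapply(cl2$assignments, function(a) a$primary, character(1))
  expect_equal(p2, p1[perm])
  expect_equal(cl1$baseline$cutoff_raw, cl2$baseline$cutoff_raw,
               tolerance = 1e-12)
})

test_that("a constant added reference raises its own baseline without creating hits", {
  # finite noise gives the betas genuine spread; at infinite SNR the
  # spiked channel is an exact constant and exceedance is float jitter
  cfg <- simulation_config(equal_distribution(injected_labels),
                           n_rois = 150, snr = 20, seed = 43)
  sim <- simulate_roi_dataset(cfg, default_lib)
  cl0 <- classify_subject(sim$spectra, default_lib, dual_pass = FALSE)
  spiked <- sim$spectra + 0.5 * default_lib$matrix[, "GCaMP6s"] /
    max(default_lib$matrix[, "GCaMP6s"])
  cl1 <- classify_subject(spiked, default_lib, dual_pass = FALSE)
  # the constant moves the baseline mean, not the exceedances: the raw
  # channel absorbs it entirely (hit rate stays at the threshold tail
  # rate), and true identities are unaffected
  expect_gt(cl1$baseline$mean_raw[["GCaMP6s"]],
            cl0$baseline$mean_raw[["GCaMP6s"]] + 0.4)
  graw <- vapply(cl1$betas, function(b) b$beta_raw[["GCaMP6s"]], numeric(1))
  expect_lt(mean(graw > cl1$baseline$cutoff_raw[["GCaMP6s"]]), 0.12)
  cl2 <- classify_subject(spiked, default_lib, dual_pass = FALSE,
                          candidates = injected_labels)
  primary <- vapply(cl2$assignments, function(a) a$primary, character(1))
  expect_gt(mean(!is.na(primary) & primary == sim$truth$class), 0.9)
})

test_that("assignment tables expose pass, identity and z-scores", {
  cfg <- simulation_config(equal_distribution(default_lib$labels),
                           n_rois = 20, snr = Inf, seed = 44)
  sim <- simulate_roi_dataset(cfg, default_lib)
  tab <- assignments_table(classify_subject(sim$spectra, default_lib))
  expect_equal(nrow(tab), 20)
  expect_true(all(c("roi_id", "pass", "primary", "secondaries", "n_hits")
                  %in% names(tab)))
  expect_true(any(grepl("^z_raw\\.", names(tab))))
})
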