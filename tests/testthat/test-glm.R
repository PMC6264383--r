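test_that("NF design matrix has the documented columns and support", {
  d <- build_nf_run()
  X <- build_nf_design_matrix(d)
  roles <- attr(X, "roles")
  expect_identical(sum(roles == "pre_onset"), 4L)
  expect_identical(roles[1:3], c("intercept", "task", "level"))
  expect_false("drift" %in% roles)
  # each pre-onset indicator spans the 10 volumes before one task onset
  onsets <- gradnf:::task_onsets(d)
  for (j in seq_along(onsets)) {
    col <- X[, paste0("pre_onset_", j)]
    expect_identical(which(col == 1) - 1L,
                     seq(onsets[j] - 10L, onsets[j] - 1L))
  }
  # task regressor peaks inside task blocks
  labels <- gradnf:::volume_labels(d)
  expect_true(labels[which.max(X[, "task"])] != "rest")
  # degenerate all-high order makes the parametric column collinear
  dd <- gradnf:::new_run_design("neurofeedback",
                                rep(c("rest", "high"), length.out = 9),
                                rep(20L, 9), scan_protocol())
  expect_error(build_nf_design_matrix(dd), "collinear")
})

test_that("localizer design matrix is intercept + task + centred drift", {
  X <- build_localizer_design_matrix(build_localizer_run())
  expect_identical(ncol(X), 3L)
  expect_equal(sum(X[, "drift"]), 0)  # orthogonal to the intercept
})

test_that("prewhitened fit reduces to OLS under white noise", {
  d <- build_nf_run()
  X <- build_nf_design_matrix(d)
  set.seed(3)
  y <- drop(X %*% c(1000, 5, 2, 0.5, -0.5, 0.2, -0.2)) + rnorm(180, 0, 2)
  fit <- fit_glm_prewhitened(y, X)
  ols <- stats::lm.fit(X, y)$coefficients
  expect_lt(abs(fit$ar1_rho_hat), 0.2)
  expect_equal(unname(fit$betas), unname(ols), tolerance = 1e-2)
  expect_identical(fit$dof, 180L - 7L)
  expect_error(fit_glm_prewhitened(y[1:50], X), "match")
})

test_that("residual AR(1) estimate recovers the generating autocorrelation", {
  d <- build_nf_run()
  X <- build_nf_design_matrix(d)
  p <- subject_sim_params(ar1_rho = 0.4, noise_sd = 6, drift_slope = 0)
  rhos <- vapply(1:300, function(i) {
    s <- simulate_roi_run(d, p, "SMA", seed = i)
    fit_glm_prewhitened(s, X)$ar1_rho_hat
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.4), 0.05)
})

test_that("prewhitened betas agree with nlme::gls under AR(1) noise", {
  skip_if_not_installed("nlme")
  d <- build_nf_run()
  X <- build_nf_design_matrix(d)
  p <- subject_sim_params(ar1_rho = 0.4, noise_sd = 6)
  s <- simulate_roi_run(d, p, "SMA", seed = 12)
  fit <- fit_glm_prewhitened(s, X)
  df <- data.frame(y = s$signal, X[, -1])
  g <- nlme::gls(y ~ task + level + pre_onset_1 + pre_onset_2 +
                   pre_onset_3 + pre_onset_4, data = df,
                 correlation = nlme::corAR1())
  expect_equal(unname(fit$betas), unname(coef(g)), tolerance = 0.02)
})

test_that("noiseless runs are recovered exactly, invariant to raw scale", {
  d <- build_nf_run(level_order = c("high", "low", "high", "low"))
  X <- build_nf_design_matrix(d)
  p <- noiseless_params(psc_sma = c(task = 1, low = 0.5, high = 1))
  s <- simulate_roi_run(d, p, "SMA", seed = 1)
  fit <- fit_glm_prewhitened(s, X)
  expect_equal(extract_psc(fit, X, "high")$psc, 1, tolerance = 1e-8)
  expect_equal(extract_psc(fit, X, "low")$psc, 0.5, tolerance = 1e-8)
  # doubled raw units: identical percent signal change
  fit2 <- fit_glm_prewhitened(2 * s$signal, X)
  expect_equal(extract_psc(fit2, X, "high")$psc, 1, tolerance = 1e-8)
  # equal level amplitudes: parametric beta vanishes, levels coincide
  p2 <- noiseless_params(psc_sma = c(task = 1, low = 0.8, high = 0.8))
  fit3 <- fit_glm_prewhitened(simulate_roi_run(d, p2, "SMA", seed = 1), X)
  expect_equal(unname(fit3$betas[3]), 0, tolerance = 1e-8)
  expect_equal(extract_psc(fit3, X, "high")$psc,
               extract_psc(fit3, X, "low")$psc, tolerance = 1e-8)
  # negative responses survive the sign convention
  fitm <- fit_glm_prewhitened(simulate_roi_run(d, p, "M1", seed = 1), X)
  expect_equal(extract_psc(fitm, X, "high")$psc, -0.2, tolerance = 1e-8)
})

test_that("localizer PSC is task beta over intercept and scale invariant", {
  loc <- build_localizer_run()
  X <- build_localizer_design_matrix(loc)
  p <- noiseless_params(psc_sma = c(task = 1.48, low = 0, high = 0))
  s <- simulate_roi_run(loc, p, "SMA", seed = 1)
  expect_equal(localizer_psc(fit_glm_prewhitened(s, X)), 1.48,
               tolerance = 1e-8)
  p0 <- noiseless_params(psc_sma = c(task = 0, low = 0, high = 0))
  s0 <- simulate_roi_run(loc, p0, "SMA", seed = 1)
  expect_equal(localizer_psc(fit_glm_prewhitened(s0, X)), 0,
               tolerance = 1e-10)
  # baseline 2000 instead of 1000: same PSC
  p$baseline_signal <- 2000
  s2 <- simulate_roi_run(loc, p, "SMA", seed = 1)
  expect_equal(localizer_psc(fit_glm_prewhitened(s2, X)), 1.48,
               tolerance = 1e-8)
  # wrong design kind is refused
  Xnf <- build_nf_design_matrix(build_nf_run())
  fit <- fit_glm_prewhitened(simulate_roi_run(build_nf_run(), p, "SMA",
                                              seed = 1), Xnf)
  expect_error(localizer_psc(fit), "localizer")
})

test_that("PSC recovery is unbiased under noise with counterbalanced orders", {
  p <- subject_sim_params(noise_sd = 5)
  p$psc_true$SMA <- c(task = 1, low = 0.5, high = 1)
  d1 <- build_nf_run(level_order = c("low", "high", "low", "high"))
  d2 <- build_nf_run(level_order = c("high", "low", "high", "low"))
  X1 <- build_nf_design_matrix(d1); X2 <- build_nf_design_matrix(d2)
  reps <- 120
  est <- t(vapply(seq_len(reps), function(i) {
    f1 <- fit_glm_prewhitened(simulate_roi_run(d1, p, "SMA", seed = 2 * i), X1)
    f2 <- fit_glm_prewhitened(simulate_roi_run(d2, p, "SMA",
                                               seed = 2 * i + 1), X2)
    c(high = mean(c(extract_psc(f1, X1, "high")$psc,
                    extract_psc(f2, X2, "high")$psc)),
      low = mean(c(extract_psc(f1, X1, "low")$psc,
                   extract_psc(f2, X2, "low")$psc)))
  }, c(high = 0, low = 0)))
  for (lv in c("high", "low")) {
    bias <- mean(est[, lv]) - p$psc_true$SMA[[lv]]
    mc_se <- sd(est[, lv]) / sqrt(reps)
    expect_lt(abs(bias), 2 * mc_se + 1e-12)
  }
})

test_that("event-related averages have the convolved-boxcar shape", {
  d <- build_nf_run()
  p0 <- noiseless_params(psc_sma = c(task = 0, low = 0, high = 0))
  flat <- event_related_average(simulate_roi_run(d, p0, "SMA", seed = 1), d)
  expect_equal(flat$mean, rep(0, nrow(flat)), tolerance = 1e-10)
  p <- noiseless_params(psc_sma = c(task = 0, low = 1, high = 1))
  s <- simulate_roi_run(d, p, "SMA", seed = 1)
  era <- event_related_average(s, d, window = c(5, 25))
  expect_identical(nrow(era), 31L)
  pre <- era$mean[era$offset_volume < 0]
  during <- era$mean[era$offset_volume %in% 10:19]
  post <- era$mean[era$offset_volume > 22]
  expect_true(all(during > 0.9))
  expect_lt(mean(abs(pre)), 0.2)
  expect_lt(mean(post), min(during))  # returns toward baseline after offset
  # negative response flips the curve by linearity
  pm <- noiseless_params(psc_sma = c(task = 0, low = -1, high = -1))
  # (percent-change normalization is only linear to first order, hence the
  # loose tolerance)
  eram <- event_related_average(simulate_roi_run(d, pm, "SMA", seed = 1), d)
  expect_equal(eram$mean, -era$mean, tolerance = 5e-3)
  expect_error(event_related_average(s, d, window = c(5, 200)), "past the end")
  # multiple subjects: within-subject error bars appear
  multi <- event_related_average(list(list(s), list(s)), d)
  expect_true("se_within" %in% names(multi))
  expect_equal(multi$se_within, rep(0, nrow(multi)), tolerance = 1e-10)
})

test_that("offline level PSC matches the online plateau PSC within 5%", {
  d <- build_nf_run()
  p <- noiseless_params(psc_sma = c(task = 1, low = 0.5, high = 1))
  s <- simulate_roi_run(d, p, "SMA", seed = 1)
  X <- build_nf_design_matrix(d)
  fit <- fit_glm_prewhitened(s, X)
  calib <- nf_calibration(c(SMA = 1, M1 = 1), "SMA")
  tr <- run_feedback_engine(s, d, calib)
  for (lv in c("low", "high")) {
    online_plateau <- mean(tr$psc_nf[plateau_index(d, lv, k = 5L)])
    offline <- extract_psc(fit, X, lv)$psc
    expect_equal(online_plateau, offline, tolerance = 0.05)
  }
})
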