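test_that("median aggregation is robust per cell and validates the grid", {
  rows <- expand.grid(subject = 1:2, region = c("SMA", "M1"),
                      condition = c("active", "passive"),
                      level = c("low", "high"), run = 1:5,
                      stringsAsFactors = FALSE)
  rows$psc <- 0
  rows$psc[rows$subject == 1 & rows$region == "SMA" &
             rows$condition == "active" & rows$level == "high"] <-
    c(1, 2, 3, 4, 100)
  gt <- aggregate_median_psc(rows)
  expect_identical(nrow(gt), 2L * 2L * 2L * 2L)
  expect_equal(gt$median_psc[gt$subject == 1 & gt$region == "SMA" &
                               gt$condition == "active" &
                               gt$level == "high"], 3)
  # single run: identity
  one <- rows[rows$run == 1, ]
  expect_equal(sort(aggregate_median_psc(one)$median_psc),
               sort(one$psc))
  # a missing cell is named in the error
  gone <- which(rows$subject == 1 & rows$region == "SMA" &
                  rows$condition == "active" & rows$level == "low")
  expect_error(aggregate_median_psc(rows[-gone, ]), "missing cell")
  expect_error(aggregate_median_psc(rows[, -6]), "lacks column")
})

test_that("paired and one-sample t-tests carry d = t / sqrt(n)", {
  x <- data_with_t(-2.196, 17)
  tt <- one_sample_t(x, side = "less")
  expect_equal(tt$t, -2.196, tolerance = 1e-10)
  expect_equal(tt$df, 16)
  expect_equal(tt$p, pt(-2.196, 16), tolerance = 1e-10)
  expect_equal(tt$d, -2.196 / sqrt(17))
  pt2 <- paired_t(x, rep(0, 17), side = "less")
  expect_equal(pt2$t, tt$t, tolerance = 1e-10)
  expect_equal(pt2$p, tt$p, tolerance = 1e-10)
  # d identity holds for every emitted result
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    r <- paired_t(a, b, side = sample(c("two", "less", "greater"), 1))
    expect_equal(r$d, r$t / sqrt(8))
  }
  expect_error(paired_t(1:5 + 2, 1:5, side = "greater"), "zero variance")
  expect_error(one_sample_t(rep(1, 5)), "zero variance")
})

test_that("cohens_d_from_t reproduces printed paired effect sizes", {
  expect_equal(cohens_d_from_t(-2.196, 17), -0.533, tolerance = 1e-3)
  expect_equal(cohens_d_from_t(3.006, 17), 0.729, tolerance = 1e-3)
  expect_equal(cohens_d_from_t(-3.552, 17), -0.862, tolerance = 1e-3)
  expect_equal(cohens_d_from_t(0, 10), 0)
})

test_that("2x2 RM-ANOVA matches aov strata and the F = t^2 identity", {
  set.seed(21)
  n <- 12
  gt <- expand.grid(subject = seq_len(n), region = "SMA",
                    condition = c("active", "passive"),
                    level = c("low", "high"), stringsAsFactors = FALSE)
  subj_eff <- rnorm(n, 0, 0.3)
  gt$median_psc <- 0.3 + subj_eff[gt$subject] +
    0.1 * (gt$level == "high") + rnorm(nrow(gt), 0, 0.15)
  res <- rm_anova_2x2(gt, "SMA")
  expect_identical(res$effect, c("level", "condition", "level:condition"))
  expect_true(all(res$F >= 0))
  expect_equal(res$df_num, rep(1, 3))
  expect_equal(res$df_den, rep(n - 1, 3))
  # level main effect equals the squared paired t on level cell means
  hi <- aggregate(median_psc ~ subject, gt[gt$level == "high", ], mean)
  lo <- aggregate(median_psc ~ subject, gt[gt$level == "low", ], mean)
  tt <- paired_t(hi$median_psc, lo$median_psc, side = "two")
  expect_equal(res$F[1], tt$t^2, tolerance = 1e-8)
  expect_equal(res$p[1], tt$p, tolerance = 1e-8)
  # additive noiseless data: zero interaction
  gt0 <- gt
  gt0$median_psc <- subj_eff[gt0$subject] +
    0.2 * (gt0$level == "high") + 0.05 * (gt0$condition == "active")
  res0 <- rm_anova_2x2(gt0, "SMA")
  expect_equal(res0$F[3], 0, tolerance = 1e-12)
  expect_error(rm_anova_2x2(gt[-1, ], "SMA"), "unbalanced")
  expect_error(rm_anova_2x2(gt, "M1"), "no rows")
})

test_that("omega squared is 0 for null effects and large for strong ones", {
  set.seed(8)
  n <- 14
  gt <- expand.grid(subject = seq_len(n), region = "SMA",
                    condition = c("active", "passive"),
                    level = c("low", "high"), stringsAsFactors = FALSE)
  gt$median_psc <- rnorm(nrow(gt), 0, 0.1)          # pure noise
  res_null <- rm_anova_2x2(gt, "SMA")
  expect_true(all(res_null$omega_squared < 0.2))
  gt$median_psc <- gt$median_psc + 1.0 * (gt$level == "high")
  res_eff <- rm_anova_2x2(gt, "SMA")
  expect_gt(res_eff$omega_squared[1], 0.8)
})

test_that("run trend ANOVA is flat for constant differences, rises with trend", {
  mk_rows <- function(trend) {
    rows <- expand.grid(subject = 1:8, region = "SMA", condition = "active",
                        level = c("low", "high"), run = 1:5,
                        stringsAsFactors = FALSE)
    set.seed(3)
    rows$psc <- 0.3 * (rows$level == "high") +
      trend * rows$run * (rows$level == "high") + rnorm(nrow(rows), 0, 0.05)
    rows
  }
  flat <- run_difference_trend(mk_rows(0), "SMA")
  steep <- run_difference_trend(mk_rows(0.3), "SMA")
  expect_identical(flat$effect, "run")
  expect_equal(flat$df_num, 4)
  expect_gt(steep$F, flat$F)
  expect_lt(steep$p, 0.05)
  # literally identical differences across runs: F = 0
  rows <- mk_rows(0)
  rows$psc <- 0.3 * (rows$level == "high") + as.numeric(rows$subject) / 10
  expect_equal(run_difference_trend(rows, "SMA")$F, 0, tolerance = 1e-12)
})

test_that("informed Bayes factor matches a Riemann-sum oracle and is monotone", {
  cases <- list(list(t = 3.006, n = 17, scale = 0.55, side = "greater"),
                list(t = -3.552, n = 17, scale = 1.11, side = "less"),
                list(t = 0.8, n = 10, scale = 0.4, side = "greater"))
  for (cs in cases) {
    bf <- informed_bayes_t(cs$t, cs$n, cs$scale, cs$side)$bf
    oracle <- riemann_bf(cs$t, cs$n, cs$scale, cs$side)
    expect_equal(bf, oracle, tolerance = 1e-4)
  }
  # increasing in t for a directed positive alternative
  bfs <- vapply(seq(-1, 4, by = 0.5), function(t)
    informed_bayes_t(t, 17, 0.55, "greater")$bf, numeric(1))
  expect_true(all(diff(bfs) > 0))
  # at t = 0 the data favour the null for any positive prior scale
  expect_lt(informed_bayes_t(0, 17, 0.55, "greater")$bf, 1)
  expect_lt(informed_bayes_t(0, 17, 2.0, "less")$bf, 1)
  # prior scale -> 0: the alternative collapses onto the null, BF -> 1
  expect_equal(informed_bayes_t(2.5, 17, 1e-6, "greater")$bf, 1,
               tolerance = 1e-3)
  expect_error(informed_bayes_t(2, 17, -1, "greater"))
})

test_that("prior scales derive from group localizer PSC fractions", {
  expect_equal(derive_prior_scale(1.48, 0.75), 1.11)
  expect_equal(derive_prior_scale(1.10, 0.50), 0.55)
  expect_equal(derive_prior_scale(0.9, 1.0), 0.9)
  expect_error(derive_prior_scale(-1, 0.5))
  expect_error(derive_prior_scale(1, 0))
})

test_that("FDR adjustment is BH step-up, monotone and order invariant", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.037, 0.207, 0.744, 0.077)
  adj <- fdr_adjust(p)
  expect_equal(max(adj), 0.744)
  expect_true(all(adj >= p))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  perm <- sample(seq_along(p))
  expect_equal(fdr_adjust(p[perm]), adj[perm])
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("physio correlation analysis recovers coupling sign and nulls", {
  d <- build_nf_run()
  mk_traces <- function(coupling, n_subj = 12, kind = "petco2") {
    out <- list()
    for (s in seq_len(n_subj)) for (r in 1:2) {
      tr <- simulate_physio(d, kind, coupling = coupling,
                            seed = 1000 * s + r)
      out[[length(out) + 1]] <- list(subject = s, region = "SMA",
                                     kind = kind, values = tr)
    }
    out
  }
  neg <- physio_task_analysis(mk_traces(-3), d)
  expect_lt(neg$mean_z, 0)
  expect_lt(neg$p, 0.05)
  expect_equal(neg$d, neg$t / sqrt(neg$n))
  null <- physio_task_analysis(mk_traces(0), d)
  expect_lt(abs(null$mean_z / null$sem_z), 3)
  expect_true(all(null$p_fdr >= null$p))
  # r = 0 maps to z = 0 exactly under the Fisher transform
  expect_equal(atanh(0), 0)
  # constant trace: dropped with a warning
  traces <- mk_traces(-3, n_subj = 4)
  traces[[1]]$values <- rep(38, 180)
  expect_warning(physio_task_analysis(traces, d), "constant")
  # informed BF column appears when a prior scale is supplied
  with_bf <- physio_task_analysis(mk_traces(-3, n_subj = 6), d,
                                  prior_scale = 0.5)
  expect_true("bf" %in% names(with_bf))
  expect_gt(with_bf$bf, 1)
})
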