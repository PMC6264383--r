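#' Aggregate per-run PSC estimates to subject-level medians
#'
#' For each subject x region x condition (active/passive) x level (low/high)
#' cell, the median percent signal change across runs. The resulting table is
#' the input to the 2x2 repeated-measures ANOVA and the t-test layer, which
#' require one row per cell per subject.
#'
#' @param psc_rows Data frame with columns `subject`, `region`, `condition`,
#'   `level`, `run`, `psc` (one row per run-level estimate).
#' @return A data frame of class `"group_table"` with `median_psc` per cell.
#' @export
aggregate_median_psc <- function(psc_rows) {
  req <- c("subject", "region", "condition", "level", "psc")
  missing_cols <- setdiff(req, names(psc_rows))
  if (length(missing_cols))
    stop("psc_rows lacks column(s): ", paste(missing_cols, collapse = ", "))
  agg <- stats::aggregate(psc ~ subject + region + condition + level,
                          data = psc_rows, FUN = stats::median)
  names(agg)[names(agg) == "psc"] <- "median_psc"
  ## every observed subject must fill the full region x condition x level grid
  grid <- expand.grid(subject = unique(psc_rows$subject),
                      region = unique(psc_rows$region),
                      condition = unique(psc_rows$condition),
                      level = unique(psc_rows$level),
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$subject, d$region, d$condition, d$level)
  absent <- !key(grid) %in% key(agg)
  if (any(absent)) {
    g <- grid[which(absent)[1], ]
    stop(sprintf("missing cell: subject %s, region %s, condition %s, level %s",
                 g$subject, g$region, g$condition, g$level))
  }
  agg <- agg[order(agg$subject, agg$region, agg$condition, agg$level), ]
  rownames(agg) <- NULL
  structure(agg, class = c("group_table", "data.frame"))
}

#' Paired t-test with Cohen's d
#'
#' Classical paired t-test (via [stats::t.test()]) augmented with the paired
#' Cohen's d (`d = t / sqrt(n)`), the mean difference and its standard error.
#' One-sided by default direction must be chosen explicitly via `side`.
#'
#' @param x,y Paired per-subject values (equal length >= 3).
#' @param side `"greater"` (x > y), `"less"`, or `"two"`.
#' @return An object of class `"nf_ttest"`: `t`, `df`, `p`, `d`, `side`,
#'   `mean_diff`, `sem_diff`, `n`.
#' @export
paired_t <- function(x, y, side = c("two", "greater", "less")) {
  side <- match.arg(side)
  stopifnot(length(x) == length(y), length(x) >= 3)
  d_xy <- x - y
  if (stats::sd(d_xy) == 0)
    stop("paired differences have zero variance; t statistic undefined")
  alt <- switch(side, two = "two.sided", greater = "greater", less = "less")
  ht <- stats::t.test(x, y, paired = TRUE, alternative = alt)
  n <- length(x)
  t <- unname(ht$statistic)
  structure(list(t = t, df = unname(ht$parameter), p = ht$p.value,
                 d = cohens_d_from_t(t, n), side = side,
                 mean_diff = mean(d_xy),
                 sem_diff = stats::sd(d_xy) / sqrt(n), n = n),
            class = "nf_ttest")
}

#' One-sample t-test with Cohen's d
#'
#' One-sample analogue of [paired_t()] against `mu = 0`, used e.g. for
#' testing region deactivation (mean PSC < 0) and for Fisher-z correlation
#' tests.
#'
#' @param x Per-subject values (length >= 3).
#' @param side `"greater"`, `"less"`, or `"two"`.
#' @return An `"nf_ttest"` object.
#' @export
one_sample_t <- function(x, side = c("two", "greater", "less")) {
  side <- match.arg(side)
  stopifnot(length(x) >= 3)
  if (stats::sd(x) == 0)
    stop("values have zero variance; t statistic undefined")
  alt <- switch(side, two = "two.sided", greater = "greater", less = "less")
  ht <- stats::t.test(x, mu = 0, alternative = alt)
  n <- length(x)
  t <- unname(ht$statistic)
  structure(list(t = t, df = unname(ht$parameter), p = ht$p.value,
                 d = cohens_d_from_t(t, n), side = side,
                 mean_diff = mean(x), sem_diff = stats::sd(x) / sqrt(n),
                 n = n),
            class = "nf_ttest")
}

#' @export
print.nf_ttest <- function(x, ...) {
  cat(sprintf("t(%g) = %.3f, p = %.4g (%s), Cohen's d = %.3f\n",
              x$df, x$t, x$p, x$side, x$d))
  cat(sprintf("mean difference = %.4g +- %.4g (SEM), n = %d\n",
              x$mean_diff, x$sem_diff, x$n))
  invisible(x)
}

#' Paired Cohen's d from a t statistic
#'
#' For a paired (or one-sample) design, `d = t / sqrt(n)`.
#'
#' @param t t statistic.
#' @param n Number of pairs (>= 2).
#' @return Cohen's d.
#' @export
cohens_d_from_t <- function(t, n) {
  stopifnot(n >= 2)
  t / sqrt(n)
}

#' 2x2 repeated-measures ANOVA with omega-squared
#'
#' Fits a fully within-subject two-factor ANOVA (target level x feedback
#' condition) to the subject-level median PSC table of one region, using
#' [stats::aov()] with `Error(subject/(level*condition))` strata so each
#' effect is tested against its own subject-by-effect interaction. The
#' omega-squared effect size is computed from the extracted sums of squares
#' as
#' `(SS_effect - df_effect * MS_error) / (SS_total + MS_subjects)`,
#' clipped below at 0.
#'
#' @param table A `"group_table"` from [aggregate_median_psc()].
#' @param region Region whose rows enter the ANOVA.
#' @return An object of class `"nf_anova"`: a data frame with one row per
#'   effect (`level`, `condition`, `level:condition`) and columns `F`,
#'   `df_num`, `df_den`, `p`, `omega_squared`.
#' @export
rm_anova_2x2 <- function(table, region) {
  stopifnot(all(c("subject", "region", "condition", "level", "median_psc")
                %in% names(table)))
  d <- table[table$region == region, ]
  if (!nrow(d)) stop("no rows for region ", sQuote(region))
  tab <- with(d, base::table(subject, condition, level))
  if (any(tab != 1))
    stop("unbalanced table for region ", sQuote(region),
         ": need exactly one row per subject x condition x level cell")
  d$subject <- factor(d$subject)
  d$level <- factor(d$level)
  d$condition <- factor(d$condition)
  a <- stats::aov(median_psc ~ level * condition +
                    Error(subject / (level * condition)), data = d)
  s <- summary(a)
  ## flatten stratum tables into one (term, SS, df, F, p, stratum) frame
  rows <- do.call(rbind, lapply(names(s), function(nm) {
    tb <- as.data.frame(s[[nm]][[1]])
    tb$term <- trimws(rownames(tb))
    tb$stratum <- nm
    tb
  }))
  ss_total <- sum(rows[["Sum Sq"]])
  subj_row <- rows[rows$stratum == "Error: subject" &
                     rows$term == "Residuals", ]
  ms_subj <- subj_row[["Sum Sq"]] / subj_row[["Df"]]
  effect_of <- function(term) {
    er <- rows[rows$term == term, ]
    res <- rows[rows$stratum == er$stratum & rows$term == "Residuals", ]
    ms_err <- res[["Sum Sq"]] / res[["Df"]]
    omega <- (er[["Sum Sq"]] - er[["Df"]] * ms_err) / (ss_total + ms_subj)
    f <- er[["F value"]]; p <- er[["Pr(>F)"]]
    if (er[["Sum Sq"]] <= 1e-12 * max(ss_total, 1)) {
      f <- 0; p <- 1  # no effect variance (possibly numerical dust)
    }
    data.frame(effect = term,
               F = f, df_num = er[["Df"]],
               df_den = res[["Df"]], p = p,
               omega_squared = max(0, omega))
  }
  out <- do.call(rbind, lapply(c("level", "condition", "level:condition"),
                               effect_of))
  rownames(out) <- NULL
  structure(out, region = region, class = c("nf_anova", "data.frame"))
}

#' One-way repeated-measures trend ANOVA over runs
#'
#' Tests for an effect of time (run index) on the per-run high-minus-low PSC
#' difference scores of the active runs of one region: a one-way
#' within-subject ANOVA with run as the factor.
#'
#' @param psc_rows Per-run PSC estimates (`subject`, `region`, `condition`,
#'   `level`, `run`, `psc`); only `condition == "active"` rows of `region`
#'   are used.
#' @param region Target region.
#' @return An `"nf_anova"` data frame with the single `run` effect.
#' @export
run_difference_trend <- function(psc_rows, region) {
  d <- psc_rows[psc_rows$region == region &
                  psc_rows$condition == "active", ]
  if (!nrow(d)) stop("no active runs for region ", sQuote(region))
  hi <- d[d$level == "high", c("subject", "run", "psc")]
  lo <- d[d$level == "low", c("subject", "run", "psc")]
  m <- merge(hi, lo, by = c("subject", "run"), suffixes = c("_high", "_low"))
  m$diff <- m$psc_high - m$psc_low
  counts <- base::table(m$subject)
  if (length(unique(counts)) != 1L || any(counts < 2L))
    stop("each subject needs the same number (>= 2) of active runs")
  ## global run ids differ across subjects (counterbalanced region order);
  ## the time factor is the ordinal position of the active run within subject
  m$run <- stats::ave(m$run, m$subject, FUN = rank)
  m$subject <- factor(m$subject)
  m$run <- factor(m$run)
  a <- stats::aov(diff ~ run + Error(subject / run), data = m)
  s <- summary(a)
  rows <- do.call(rbind, lapply(names(s), function(nm) {
    tb <- as.data.frame(s[[nm]][[1]])
    tb$term <- trimws(rownames(tb))
    tb$stratum <- nm
    tb
  }))
  er <- rows[rows$term == "run", ]
  res <- rows[rows$stratum == er$stratum & rows$term == "Residuals", ]
  subj <- rows[rows$stratum == "Error: subject" & rows$term == "Residuals", ]
  ms_err <- res[["Sum Sq"]] / res[["Df"]]
  ss_total <- sum(rows[["Sum Sq"]])
  omega <- (er[["Sum Sq"]] - er[["Df"]] * ms_err) /
    (ss_total + subj[["Sum Sq"]] / subj[["Df"]])
  f <- er[["F value"]]; p <- er[["Pr(>F)"]]
  if (er[["Sum Sq"]] <= 1e-12 * max(ss_total, 1)) {
    f <- 0; p <- 1  # constant difference scores across runs: no trend
  }
  out <- data.frame(effect = "run", F = f,
                    df_num = er[["Df"]], df_den = res[["Df"]],
                    p = p, omega_squared = max(0, omega))
  structure(out, region = region, class = c("nf_anova", "data.frame"))
}

#' Informed half-normal Bayes factor for a t statistic
#'
#' Directed Bayes factor of an informed alternative against the point null,
#' computed from the observed t statistic of a paired (or one-sample) design.
#' Under the alternative the standardized effect delta carries a half-normal
#' prior with scale `prior_scale`, truncated to the hypothesized direction;
#' the likelihood of delta is the noncentral t density with `df = n - 1` and
#' noncentrality `delta * sqrt(n)`. The Bayes factor is
#'
#' `BF = integral f(t | delta sqrt(n), df) half-N(delta; prior_scale) d delta
#'       / f(t | 0, df)`,
#'
#' evaluated by adaptive quadrature to relative tolerance `rel_tol`.
#'
#' @param t Observed t statistic.
#' @param n Number of pairs (>= 2).
#' @param prior_scale Scale of the half-normal prior on delta (> 0).
#' @param side `"greater"` (delta > 0) or `"less"` (delta < 0).
#' @param rel_tol Relative integration tolerance.
#' @return An object of class `"nf_bayes"`: `bf`, `prior_scale`, `side`,
#'   `t_input`, `n_input`, `abs_error` (quadrature error estimate).
#' @examples
#' informed_bayes_t(t = -3.552, n = 17, prior_scale = 1.11, side = "less")
#' @export
informed_bayes_t <- function(t, n, prior_scale,
                             side = c("greater", "less"),
                             rel_tol = 1e-6) {
  side <- match.arg(side)
  stopifnot(is.finite(t), n >= 2, prior_scale > 0)
  df <- n - 1
  sgn <- if (side == "greater") 1 else -1
  ## substitute delta = prior_scale * u so the prior mass is well scaled for
  ## any prior width; the direction is folded into the sign of the ncp
  integrand <- function(u)
    stats::dt(t, df = df, ncp = sgn * prior_scale * u * sqrt(n)) *
    2 * stats::dnorm(u)
  quad <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = rel_tol,
                     stop.on.error = TRUE),
    error = function(e) stop("Bayes factor integration failed: ",
                             conditionMessage(e)))
  bf <- quad$value / stats::dt(t, df = df)
  structure(list(bf = bf, prior_scale = prior_scale, side = side,
                 t_input = t, n_input = n, abs_error = quad$abs.error),
            class = "nf_bayes")
}

#' @export
print.nf_bayes <- function(x, ...) {
  tag <- if (x$side == "greater") "BF+0" else "BF-0"
  cat(sprintf("%s = %.3f  [half-normal prior scale %.3g, t = %.3f, n = %d]\n",
              tag, x$bf, x$prior_scale, x$t_input, x$n_input))
  invisible(x)
}

#' Prior scale from a group localizer PSC
#'
#' The informed prior scale is a fixed fraction of the group-mean localizer
#' percent signal change of the relevant region: 75% of the M1 PSC for the
#' deactivation tests, 50% of the SMA PSC for the level-difference test
#' (mirroring the 50% *low* target scaling).
#'
#' @param group_psc Group-mean localizer PSC (> 0).
#' @param fraction Scaling fraction in (0, 1].
#' @return `group_psc * fraction`.
#' @examples
#' derive_prior_scale(1.48, 0.75)  # 1.11
#' derive_prior_scale(1.10, 0.50)  # 0.55
#' @export
derive_prior_scale <- function(group_psc, fraction) {
  stopifnot(group_psc > 0, fraction > 0, fraction <= 1)
  group_psc * fraction
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjusted p-values via
#' [stats::p.adjust()]; adjusted values are monotone and never smaller than
#' the raw values.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Physiological-confound correlation analysis
#'
#' For each run, the (demeaned) physiological trace is convolved with the
#' hemodynamic kernel and Pearson-correlated with the convolved task
#' predictor; correlations are Fisher-z transformed, averaged across runs
#' within subject, and each trace x region combination is tested against
#' zero with a one-sample t-test (two-sided by default). P-values are FDR
#' corrected across the combinations. A constant trace yields an undefined
#' correlation and is dropped with a warning.
#'
#' @param traces A data-frame-like list of entries, each a list with
#'   `subject`, `region` (target region grouping), `kind` (`"petco2"` or
#'   `"heart_rate"`), and `values` (per-TR trace of one run).
#' @param design The shared `"run_design"` of the runs.
#' @param hrf Kernel from [make_hrf()]; built from the design's TR if `NULL`.
#' @param side Sidedness of the group t-tests.
#' @param prior_scale Optional half-normal prior scale; when given, an
#'   informed directed Bayes factor (direction = sign of the group mean z) is
#'   added per combination.
#' @return A data frame of class `"physio_corr"`: one row per region x kind
#'   with `mean_z`, `sem_z`, `t`, `df`, `p`, `p_fdr`, `d`, and optionally
#'   `bf`.
#' @export
physio_task_analysis <- function(traces, design, hrf = NULL,
                                 side = c("two", "greater", "less"),
                                 prior_scale = NULL) {
  side <- match.arg(side)
  stopifnot(inherits(design, "run_design"))
  if (is.null(hrf)) hrf <- make_hrf(design$protocol$tr_seconds)
  task_pred <- convolve_causal(
    as.numeric(volume_labels(design) != "rest"), hrf)

  per_run <- do.call(rbind, lapply(traces, function(tr) {
    v <- if (is.numeric(tr$values)) tr$values else tr$values$value
    if (length(v) != design$total_volumes)
      stop("trace length does not match the design")
    if (stats::sd(v) == 0) {
      warning("constant physiological trace (subject ", tr$subject,
              ", ", tr$kind, "); correlation undefined, dropped")
      return(NULL)
    }
    conv <- convolve_causal(v - mean(v), hrf)
    r <- stats::cor(conv, task_pred)
    data.frame(subject = tr$subject, region = tr$region, kind = tr$kind,
               r = r, z = atanh(r), stringsAsFactors = FALSE)
  }))
  if (is.null(per_run) || !nrow(per_run)) stop("no usable traces")

  subj_z <- stats::aggregate(z ~ subject + region + kind, per_run, mean)
  combos <- unique(subj_z[c("region", "kind")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- subj_z$region == combos$region[i] & subj_z$kind == combos$kind[i]
    z <- subj_z$z[sel]
    tt <- one_sample_t(z, side = side)
    row <- data.frame(region = combos$region[i], kind = combos$kind[i],
                      n = tt$n, mean_z = tt$mean_diff, sem_z = tt$sem_diff,
                      t = tt$t, df = tt$df, p = tt$p, d = tt$d,
                      stringsAsFactors = FALSE)
    if (!is.null(prior_scale)) {
      dir <- if (tt$mean_diff >= 0) "greater" else "less"
      row$bf <- informed_bayes_t(tt$t, tt$n, prior_scale, side = dir)$bf
    }
    row
  }))
  out$p_fdr <- fdr_adjust(out$p)
  rownames(out) <- NULL
  structure(out, class = c("physio_corr", "data.frame"))
}
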