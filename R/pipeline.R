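#' Configuration for a full simulated study
#'
#' Collects every knob of the end-to-end pipeline in one validated object.
#' Defaults reproduce the emulated study conditions: 17 subjects, 5
#' neurofeedback runs per target region, TR 1.55 s, and the default
#' [subject_sim_params()] effect structure.
#'
#' @param n_subjects Cohort size.
#' @param seed Root seed; every stochastic stage derives its own seed from it
#'   via [child_seed()].
#' @param protocol A [scan_protocol()].
#' @param template A [subject_sim_params()].
#' @param between_subject_sd Between-subject SD of true PSC values (percent).
#' @param n_runs_per_region Neurofeedback runs per target region.
#' @param prior_fractions Named vector: fraction of the group localizer PSC
#'   used as informed-prior scale for the M1 deactivation tests (`M1`) and
#'   the SMA level test (`SMA`).
#' @param physio_side Sidedness of the physiological correlation t-tests.
#' @param out_dir Optional output directory for the CSV/JSON bundle.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(n_subjects = 17L, seed = 1L,
                         protocol = scan_protocol(),
                         template = subject_sim_params(),
                         between_subject_sd = 0.10,
                         n_runs_per_region = 5L,
                         prior_fractions = c(M1 = 0.75, SMA = 0.50),
                         physio_side = "two",
                         out_dir = NULL) {
  stopifnot(n_subjects >= 2, n_runs_per_region >= 1,
            all(c("M1", "SMA") %in% names(prior_fractions)))
  structure(list(n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), protocol = protocol,
                 template = template,
                 between_subject_sd = between_subject_sd,
                 n_runs_per_region = as.integer(n_runs_per_region),
                 prior_fractions = prior_fractions,
                 physio_side = physio_side, out_dir = out_dir),
            class = "study_config")
}

#' Offline analysis of a simulated cohort
#'
#' Runs the per-subject analysis chain on an [simulate_cohort()] object:
#' localizer GLM per region (giving PSC_LOC calibrations), the online
#' feedback engine over each neurofeedback run's target-region series, and
#' the prewhitened neurofeedback GLM with level-wise PSC extraction for both
#' regions of every run. A region's estimates are labelled `active` in runs
#' where it drove the feedback and `passive` otherwise.
#'
#' @param cohort An `"nf_cohort"`.
#' @return A list with `psc_rows` (per-run PSC table: subject, region,
#'   condition, level, run, psc), `calibrations` (per subject), and
#'   `feedback_traces` (per subject, per run).
#' @export
analyze_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "nf_cohort"))
  protocol <- cohort$protocol
  hrf <- make_hrf(protocol$tr_seconds)
  regions <- names(cohort$subjects[[1]]$localizer$series)

  res <- lapply(cohort$subjects, function(s) {
    loc_X <- build_localizer_design_matrix(s$localizer$design, hrf)
    psc_loc <- vapply(regions, function(rg)
      localizer_psc(fit_glm_prewhitened(s$localizer$series[[rg]], loc_X)),
      numeric(1))
    traces <- lapply(s$nf_runs, function(run) {
      calib <- nf_calibration(psc_loc, run$target_region)
      run_feedback_engine(run$series[[run$target_region]], run$design, calib)
    })
    rows <- do.call(rbind, lapply(s$nf_runs, function(run) {
      X <- build_nf_design_matrix(run$design, hrf)
      do.call(rbind, lapply(regions, function(rg) {
        fit <- fit_glm_prewhitened(run$series[[rg]], X)
        do.call(rbind, lapply(c("low", "high"), function(lv)
          data.frame(subject = s$subject_id, region = rg,
                     condition = if (rg == run$target_region) "active"
                                 else "passive",
                     level = lv, run = run$run,
                     psc = extract_psc(fit, X, lv)$psc,
                     stringsAsFactors = FALSE)))
      }))
    }))
    list(psc_loc = psc_loc, traces = traces, rows = rows)
  })

  list(psc_rows = do.call(rbind, lapply(res, `[[`, "rows")),
       calibrations = lapply(res, `[[`, "psc_loc"),
       feedback_traces = lapply(res, `[[`, "traces"))
}

#' Run the full simulated study end to end
#'
#' simulate -> feedback -> offline GLM -> group statistics, deterministically
#' from the config's seed. The report contains the group localizer PSC means,
#' the 2x2 repeated-measures ANOVA per region, the pooled high-vs-low level
#' t-test and its informed Bayes factor, the M1 deactivation t-tests and
#' Bayes factors per condition, the run-trend ANOVAs, and the physiological
#' correlation table.
#'
#' @param config A [study_config()].
#' @return A list of class `"study_report"` with elements `config`, `cohort`,
#'   `analysis`, `group_table`, `localizer_psc` (group means), `anova`,
#'   `level_test`, `deactivation`, `run_trend`, `physio`, and `manifest`.
#' @export
run_full_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  cohort <- simulate_cohort(config$n_subjects, config$template,
                            config$between_subject_sd,
                            seed = child_seed(config$seed, 100),
                            protocol = config$protocol,
                            n_runs_per_region = config$n_runs_per_region)
  analysis <- analyze_cohort(cohort)
  gt <- aggregate_median_psc(analysis$psc_rows)
  regions <- names(cohort$subjects[[1]]$localizer$series)

  loc_mat <- do.call(rbind, analysis$calibrations)
  loc_mean <- colMeans(loc_mat)
  prior_scales <- c(
    M1 = derive_prior_scale(loc_mean[["M1"]], config$prior_fractions[["M1"]]),
    SMA = derive_prior_scale(loc_mean[["SMA"]],
                             config$prior_fractions[["SMA"]]))

  anovas <- lapply(stats::setNames(regions, regions),
                   function(rg) rm_anova_2x2(gt, rg))

  ## SMA level effect: high vs low pooled over conditions, hypothesis high>low
  sma <- gt[gt$region == "SMA", ]
  cell <- function(d, lv) {
    x <- stats::aggregate(median_psc ~ subject, d[d$level == lv, ], mean)
    x$median_psc[order(x$subject)]
  }
  level_t <- paired_t(cell(sma, "high"), cell(sma, "low"), side = "greater")
  level_bf <- informed_bayes_t(level_t$t, level_t$n, prior_scales[["SMA"]],
                               side = "greater")

  ## M1 deactivation: per condition, mean over levels, hypothesis < 0
  m1 <- gt[gt$region == "M1", ]
  deact <- lapply(stats::setNames(unique(m1$condition), unique(m1$condition)),
                  function(cond) {
    x <- stats::aggregate(median_psc ~ subject, m1[m1$condition == cond, ],
                          mean)
    tt <- one_sample_t(x$median_psc[order(x$subject)], side = "less")
    list(t_test = tt,
         bayes = informed_bayes_t(tt$t, tt$n, prior_scales[["M1"]],
                                  side = "less"))
  })

  trend <- lapply(stats::setNames(regions, regions),
                  function(rg) run_difference_trend(analysis$psc_rows, rg))

  ## physio: group runs by target region; the task predictor is shared
  nf_design <- cohort$subjects[[1]]$nf_runs[[1]]$design
  traces <- unlist(lapply(cohort$subjects, function(s)
    lapply(s$nf_runs, function(run)
      lapply(names(run$physio), function(k)
        list(subject = s$subject_id, region = run$target_region, kind = k,
             values = run$physio[[k]])))), recursive = FALSE)
  traces <- unlist(traces, recursive = FALSE)
  physio <- physio_task_analysis(traces, nf_design,
                                 side = config$physio_side)

  report <- structure(
    list(config = config, cohort = cohort, analysis = analysis,
         group_table = gt, localizer_psc = loc_mean,
         prior_scales = prior_scales, anova = anovas,
         level_test = list(t_test = level_t, bayes = level_bf),
         deactivation = deact, run_trend = trend, physio = physio),
    class = "study_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Graded neurofeedback study report\n")
  cat(sprintf("  subjects: %d, NF runs/region: %d, seed: %d\n",
              x$config$n_subjects, x$config$n_runs_per_region,
              x$config$seed))
  cat(sprintf("  localizer PSC (group mean): %s\n",
              paste(sprintf("%s %.3f", names(x$localizer_psc),
                            x$localizer_psc), collapse = ", ")))
  cat("  SMA level effect (high > low, pooled): ")
  print(x$level_test$t_test)
  cat(sprintf("    informed BF+0 = %.3f (prior scale %.3f)\n",
              x$level_test$bayes$bf, x$level_test$bayes$prior_scale))
  for (cond in names(x$deactivation)) {
    dd <- x$deactivation[[cond]]
    cat(sprintf("  M1 %s deactivation: t(%g) = %.3f, p = %.4g, BF-0 = %.3f\n",
                cond, dd$t_test$df, dd$t_test$t, dd$t_test$p, dd$bayes$bf))
  }
  for (rg in names(x$anova)) {
    lv <- x$anova[[rg]][x$anova[[rg]]$effect == "level", ]
    cat(sprintf("  %s ANOVA level effect: F(%d,%d) = %.3f, p = %.4g, w2 = %.3f\n",
                rg, lv$df_num, lv$df_den, lv$F, lv$p, lv$omega_squared))
  }
  invisible(x)
}

## serialize the report bundle: CSV tables + JSON summary + manifest
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$analysis$psc_rows,
                   file.path(out_dir, "psc_runs.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$group_table),
                   file.path(out_dir, "group_table.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$physio),
                   file.path(out_dir, "physio_correlations.csv"),
                   row.names = FALSE)
  summ <- list(
    localizer_psc = as.list(report$localizer_psc),
    prior_scales = as.list(report$prior_scales),
    level_test = list(t = report$level_test$t_test$t,
                      df = report$level_test$t_test$df,
                      p = report$level_test$t_test$p,
                      d = report$level_test$t_test$d,
                      bf = report$level_test$bayes$bf),
    deactivation = lapply(report$deactivation, function(dd)
      list(t = dd$t_test$t, df = dd$t_test$df, p = dd$t_test$p,
           d = dd$t_test$d, bf = dd$bayes$bf)),
    anova = lapply(report$anova, as.data.frame),
    run_trend = lapply(report$run_trend, as.data.frame))
  jsonlite::write_json(summ, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- report$config
  cfg$protocol <- unclass(cfg$protocol)
  cfg$template <- unclass(cfg$template)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_path)),
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("gradnf")),
                   files = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Miniature cohort for tests and examples
#'
#' A 3-subject cohort with 2 neurofeedback runs per target region and the
#' default effect structure; generates in a few seconds and exercises every
#' downstream stage.
#'
#' @param seed Root seed.
#' @return An `"nf_cohort"`.
#' @export
make_fixtures <- function(seed = 0L) {
  simulate_cohort(3L, subject_sim_params(), between_subject_sd = 0.05,
                  seed = seed, n_runs_per_region = 2L)
}
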