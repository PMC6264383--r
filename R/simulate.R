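#' Generative parameters for one simulated subject
#'
#' Holds everything the ROI time-series generator needs for one subject: the
#' raw-unit baseline signal, the true percent signal change (PSC) of each
#' region in each condition, the AR(1) noise model, a linear drift, and the
#' task-coupling amplitudes of the physiological traces.
#'
#' The default effect structure emulates a graded kinesthetic motor-imagery
#' experiment: the supplementary motor area (SMA) responds positively during
#' imagery with a high-vs-low level difference of 0.087 PSC, primary motor
#' cortex (M1) deactivates mildly, and during the motor-execution localizer
#' both regions respond strongly (M1 1.48, SMA 1.10 PSC).
#'
#' @param baseline_signal Raw-unit mean signal (arbitrary scanner units).
#' @param psc_true Named list per region (`SMA`, `M1`), each a named numeric
#'   vector with entries `task` (localizer), `low` and `high` (neurofeedback
#'   levels), in percent. Negative entries model deactivation.
#' @param ar1_rho Lag-1 autocorrelation of the noise, in (-1, 1).
#' @param noise_sd Marginal standard deviation of the AR(1) noise, raw units.
#' @param drift_slope Linear drift, raw units per volume.
#' @param physio Named list per trace kind (`petco2`, `heart_rate`) with
#'   entries `mean`, `sd` (slow-fluctuation SD), and `coupling` (task-locked
#'   amplitude, trace units).
#' @return An object of class `"subject_sim_params"`.
#' @export
subject_sim_params <- function(
    baseline_signal = 1000,
    psc_true = list(
      SMA = c(task = 1.10, low = 0.25, high = 0.337),
      M1  = c(task = 1.48, low = -0.15, high = -0.15)),
    ar1_rho = 0.3,
    noise_sd = 5,
    drift_slope = 0.01,
    physio = list(
      petco2     = c(mean = 38, sd = 1.0, coupling = -0.18),
      heart_rate = c(mean = 65, sd = 2.0, coupling = -0.20))) {
  stopifnot(baseline_signal > 0, noise_sd >= 0, abs(ar1_rho) < 1)
  stopifnot(is.list(psc_true), all(vapply(psc_true, is.numeric, logical(1))))
  structure(list(baseline_signal = baseline_signal,
                 psc_true = psc_true,
                 ar1_rho = ar1_rho,
                 noise_sd = noise_sd,
                 drift_slope = drift_slope,
                 physio = physio),
            class = "subject_sim_params")
}

#' Simulate one ROI-mean BOLD run
#'
#' Generates a per-TR region-of-interest mean signal for one run:
#' `baseline * (1 + sum_c psc_true[c]/100 * conv(boxcar_c, hrf))
#'  + drift_slope * volume + AR(1) noise`,
#' where the sum runs over the task conditions present in the design (the
#' `task` blocks of a localizer, the `low`/`high` blocks of a neurofeedback
#' run). Deterministic given `seed`.
#'
#' @param design A `"run_design"`.
#' @param params A [subject_sim_params()].
#' @param region Region name; must be an entry of `params$psc_true`.
#' @param hrf Kernel from [make_hrf()]; built from the design's TR when `NULL`.
#' @param seed Integer seed.
#' @return A data frame of class `"roi_timeseries"` with columns `volume`
#'   (0-based), `signal`, `block_type`, and attributes `region` and `design`.
#' @export
simulate_roi_run <- function(design, params, region, hrf = NULL, seed = 1L) {
  stopifnot(inherits(design, "run_design"),
            inherits(params, "subject_sim_params"))
  if (!region %in% names(params$psc_true))
    stop("unknown region ", sQuote(region), "; params define: ",
         paste(names(params$psc_true), collapse = ", "))
  if (is.null(hrf)) hrf <- make_hrf(design$protocol$tr_seconds)
  n <- design$total_volumes
  labels <- volume_labels(design)
  psc <- params$psc_true[[region]]
  resp <- numeric(n)
  for (cond in setdiff(unique(labels), "rest")) {
    if (!cond %in% names(psc))
      stop("params$psc_true$", region, " has no entry for condition ",
           sQuote(cond))
    resp <- resp + psc[[cond]] / 100 * convolve_causal(as.numeric(labels == cond), hrf)
  }
  local_rng(seed)
  noise <- ar1_noise(n, params$ar1_rho, params$noise_sd)
  sig <- params$baseline_signal * (1 + resp) +
    params$drift_slope * (seq_len(n) - 1) + noise
  out <- data.frame(volume = seq_len(n) - 1L, signal = sig,
                    block_type = labels, stringsAsFactors = FALSE)
  structure(out, region = region, design = design,
            class = c("roi_timeseries", "data.frame"))
}

#' Simulate a physiological trace for one run
#'
#' Generates a per-TR end-tidal CO2 (mmHg) or heart-rate (bpm) trace:
#' subject-typical mean + slowly varying AR(1) fluctuation + `coupling` times
#' the task boxcar. A nonzero coupling models physiology that co-varies with
#' the cognitive demands of the task.
#'
#' @param design A `"run_design"`.
#' @param kind `"petco2"` or `"heart_rate"`.
#' @param coupling Task-locked amplitude in trace units (0 = uncoupled).
#' @param seed Integer seed.
#' @param mean,sd Trace mean and slow-fluctuation SD; defaults depend on
#'   `kind` (38 +- 1 mmHg for CO2, 65 +- 2 bpm for heart rate).
#' @return A data frame of class `"physio_trace"` with columns `volume` and
#'   `value`, and attributes `kind` and `coupling`.
#' @export
simulate_physio <- function(design, kind = c("petco2", "heart_rate"),
                            coupling = 0, seed = 1L,
                            mean = NULL, sd = NULL) {
  stopifnot(inherits(design, "run_design"), is.finite(coupling))
  kind <- match.arg(kind)
  defaults <- list(petco2 = c(mean = 38, sd = 1.0),
                   heart_rate = c(mean = 65, sd = 2.0))[[kind]]
  if (is.null(mean)) mean <- defaults[["mean"]]
  if (is.null(sd)) sd <- defaults[["sd"]]
  n <- design$total_volumes
  box <- as.numeric(volume_labels(design) != "rest")
  local_rng(seed)
  slow <- ar1_noise(n, 0.95, sd)   # high rho: breathing/heart drift is slow
  vals <- mean + slow + coupling * box
  structure(data.frame(volume = seq_len(n) - 1L, value = vals),
            kind = kind, coupling = coupling,
            class = c("physio_trace", "data.frame"))
}

#' Simulate a full cohort
#'
#' Draws per-subject generative parameters around a template, lays out each
#' subject's session with [assign_counterbalancing()] (one localizer run, then
#' the counterbalanced neurofeedback runs), and simulates both regions' ROI
#' series plus physiological traces for every run. Deterministic given `seed`.
#'
#' Between-subject variability perturbs every `psc_true` entry with
#' independent Gaussian noise of SD `between_subject_sd` (percent units).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param template A [subject_sim_params()] giving the population-level
#'   parameter means.
#' @param between_subject_sd SD of subject-level deviations of `psc_true`
#'   entries, in percent.
#' @param seed Root seed; all per-subject and per-run seeds derive from it via
#'   [child_seed()].
#' @param protocol A [scan_protocol()].
#' @param n_runs_per_region Neurofeedback runs per target region (default 5).
#' @param out_dir Optional directory: when given, each run is written as a
#'   CSV (`volume, signal_SMA, signal_M1, petco2, heart_rate`), an events TSV,
#'   and a JSON cohort manifest.
#' @return An object of class `"nf_cohort"`: a list with `protocol`, `plans`,
#'   and `subjects`, where each subject holds `params`, a `localizer` run and
#'   `nf_runs` (each run a list with `design`, `target_region`, `series` per
#'   region and `physio` per trace kind).
#' @export
simulate_cohort <- function(n_subjects, template = subject_sim_params(),
                            between_subject_sd = 0.10, seed = 1L,
                            protocol = scan_protocol(),
                            n_runs_per_region = 5L,
                            out_dir = NULL) {
  stopifnot(n_subjects >= 2)
  plans <- assign_counterbalancing(n_subjects, seed = child_seed(seed, 1),
                                   n_runs_per_region = n_runs_per_region)
  hrf <- make_hrf(protocol$tr_seconds)
  loc_design <- build_localizer_run(protocol)
  regions <- names(template$psc_true)

  subjects <- lapply(seq_len(n_subjects), function(i) {
    sseed <- child_seed(seed, 2, i)
    local_rng(sseed)
    psc_i <- lapply(template$psc_true, function(v)
      v + stats::rnorm(length(v), 0, between_subject_sd))
    params_i <- template
    params_i$psc_true <- psc_i

    sim_run <- function(design, run_offset) {
      series <- lapply(seq_along(regions), function(r)
        simulate_roi_run(design, params_i, regions[r], hrf,
                         seed = child_seed(sseed, 10 + run_offset, r)))
      names(series) <- regions
      physio <- lapply(c(petco2 = "petco2", heart_rate = "heart_rate"),
                       function(k)
        simulate_physio(design, k,
                        coupling = params_i$physio[[k]][["coupling"]],
                        seed = child_seed(sseed, 40 + run_offset,
                                          match(k, c("petco2", "heart_rate")))))
      list(design = design, series = series, physio = physio)
    }

    loc <- sim_run(loc_design, 0L)
    plan <- plans[[i]]
    nf_runs <- lapply(seq_len(nrow(plan$runs)), function(j) {
      d <- build_nf_run(protocol, plan$runs$level_order[[j]])
      run <- sim_run(d, j)
      run$run <- j
      run$target_region <- plan$runs$target_region[j]
      run
    })
    list(subject_id = i, params = params_i, localizer = loc,
         nf_runs = nf_runs)
  })

  cohort <- structure(list(protocol = protocol, plans = plans,
                           subjects = subjects, seed = seed),
                      class = "nf_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.nf_cohort <- function(x, ...) {
  cat(sprintf("<nf_cohort: %d subjects, %d NF runs each, seed %d>\n",
              length(x$subjects), length(x$subjects[[1]]$nf_runs), x$seed))
  invisible(x)
}

## CSV/TSV/JSON bundle for a cohort
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(n_subjects = length(cohort$subjects),
                   seed = cohort$seed,
                   tr_seconds = cohort$protocol$tr_seconds,
                   runs = list())
  write_run <- function(run, stem) {
    df <- data.frame(volume = run$series[[1]]$volume)
    for (rg in names(run$series))
      df[[paste0("signal_", rg)]] <- run$series[[rg]]$signal
    df$petco2 <- run$physio$petco2$value
    df$heart_rate <- run$physio$heart_rate$value
    utils::write.csv(df, file.path(out_dir, paste0(stem, ".csv")),
                     row.names = FALSE)
    write_events_tsv(run$design, file.path(out_dir, paste0(stem, "_events.tsv")))
    stem
  }
  for (s in cohort$subjects) {
    id <- sprintf("sub-%02d", s$subject_id)
    stems <- c(write_run(s$localizer, paste0(id, "_loc")),
               vapply(s$nf_runs, function(r)
                 write_run(r, sprintf("%s_nf-%02d_%s", id, r$run,
                                      r$target_region)),
                 character(1)))
    manifest$runs[[id]] <- stems
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
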