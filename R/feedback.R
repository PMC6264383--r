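#' Localizer calibration for feedback scaling
#'
#' Stores the localizer percent signal change (PSC_LOC) of each region and
#' which region drives the thermometer. Feedback during a run is expressed in
#' units of the target region's PSC_LOC, so one thermometer segment equals
#' `segment_fraction * PSC_LOC` percent signal change.
#'
#' @param psc_loc Named numeric vector of localizer PSC per region (percent).
#' @param region Feedback target region; its `psc_loc` must be positive.
#' @return An object of class `"nf_calibration"`.
#' @export
nf_calibration <- function(psc_loc, region) {
  stopifnot(is.numeric(psc_loc), all(is.finite(psc_loc)),
            region %in% names(psc_loc))
  if (psc_loc[[region]] <= 0)
    stop("feedback target ", sQuote(region),
         " has non-positive localizer PSC (", psc_loc[[region]],
         "); calibration invalid")
  structure(list(psc_loc = psc_loc, region = region),
            class = "nf_calibration")
}

#' Online baseline: median of the last 10 rest volumes
#'
#' The online baseline for a task block is the median raw ROI value over the
#' second half (last 10 TRs) of the immediately preceding rest period.
#'
#' @param rest_values Raw signal values of one complete rest period (>= 10).
#' @return The median of the last 10 values.
#' @export
compute_baseline <- function(rest_values) {
  if (length(rest_values) < 10L)
    stop("rest period has ", length(rest_values),
         " values; at least 10 are required for the online baseline")
  stats::median(utils::tail(rest_values, 10L))
}

#' Online percent signal change
#'
#' `PSC_NF = (val - baseline) * 100 / baseline`, where `val` is the mean of
#' the last three consecutive raw ROI values.
#'
#' @param last_three Numeric vector of the three most recent raw values.
#' @param baseline Baseline from [compute_baseline()]; must be positive.
#' @return Percent signal change (scalar).
#' @export
compute_psc_nf <- function(last_three, baseline) {
  stopifnot(length(last_three) == 3L, all(is.finite(last_three)))
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline must be positive and finite; got ", baseline)
  (mean(last_three) - baseline) * 100 / baseline
}

#' Map online PSC to thermometer segments
#'
#' One segment represents `segment_fraction` (default 10%) of the target
#' region's localizer PSC. The continuous segment value
#' `psc_nf / (segment_fraction * psc_loc)` is rounded to the nearest integer
#' (half away from zero; `rounding = "floor"` selects truncation instead) and
#' clamped to `[0, n_segments]`.
#'
#' @param psc_nf Online percent signal change.
#' @param psc_loc Localizer PSC of the feedback target region; must be > 0.
#' @param protocol A [scan_protocol()].
#' @param rounding `"nearest"` (default) or `"floor"`.
#' @return Integer number of lit segments.
#' @export
map_to_segments <- function(psc_nf, psc_loc, protocol = scan_protocol(),
                            rounding = c("nearest", "floor")) {
  if (!is.finite(psc_loc) || psc_loc <= 0)
    stop("psc_loc must be positive; calibration invalid")
  rounding <- match.arg(rounding)
  cont <- psc_nf / (protocol$segment_fraction * psc_loc)
  k <- switch(rounding, nearest = round_half_up(cont), floor = floor(cont))
  as.integer(pmin(pmax(k, 0L), protocol$n_segments))
}

#' Thermometer segment of a target level
#'
#' The *low* and *high* targets sit at `low_target_fraction` and
#' `high_target_fraction` of PSC_LOC; divided by the per-segment fraction this
#' gives segments 5 and 10 for the defaults.
#'
#' @param level `"low"` or `"high"`.
#' @param protocol A [scan_protocol()].
#' @return Integer segment index of the target arrow.
#' @export
target_segments <- function(level, protocol = scan_protocol()) {
  frac <- switch(level,
                 low = protocol$low_target_fraction,
                 high = protocol$high_target_fraction,
                 stop("unknown target level ", sQuote(level)))
  as.integer(round_half_up(frac / protocol$segment_fraction))
}

#' Run the causal online feedback engine over one run
#'
#' Replays the real-time feedback computation volume by volume: during each
#' rest block the raw values are accumulated and, at the rest-to-task
#' transition, the baseline is set to the median of that rest block's last 10
#' values; during task blocks each volume emits the moving-average online PSC
#' ([compute_psc_nf()] over the last three acquired values) and its
#' thermometer segments; rest volumes carry no feedback (the thermometer
#' stays empty, recorded as `NA`).
#'
#' With `window = "straddle"` (the replicated online behaviour) the 3-volume
#' moving window at a task block's first two volumes includes trailing rest
#' volumes; `window = "restart"` restricts it to values acquired since block
#' onset.
#'
#' @param series A `"roi_timeseries"` (or numeric vector) of raw ROI values.
#' @param design The run's `"run_design"`; must begin with a rest block.
#' @param calibration An [nf_calibration()].
#' @param window `"straddle"` or `"restart"`.
#' @param rounding Passed to [map_to_segments()].
#' @return A data frame of class `"feedback_trace"` with one row per volume:
#'   `volume`, `block_type`, `val`, `baseline`, `psc_nf`, `segments`,
#'   `target_segments` (all `NA` on rest volumes).
#' @export
run_feedback_engine <- function(series, design, calibration,
                                window = c("straddle", "restart"),
                                rounding = c("nearest", "floor")) {
  stopifnot(inherits(design, "run_design"),
            inherits(calibration, "nf_calibration"))
  window <- match.arg(window)
  rounding <- match.arg(rounding)
  raw <- if (is.numeric(series)) series else series$signal
  n <- design$total_volumes
  if (length(raw) != n)
    stop("series has ", length(raw), " volumes but the design expects ", n)
  labels <- volume_labels(design)
  if (labels[1] != "rest") stop("run must begin with a rest block")
  protocol <- design$protocol
  psc_loc <- calibration$psc_loc[[calibration$region]]

  baseline <- NA_real_
  rest_buf <- numeric(0)
  block_onset <- 1L
  out <- data.frame(volume = seq_len(n) - 1L, block_type = labels,
                    val = NA_real_, baseline = NA_real_, psc_nf = NA_real_,
                    segments = NA_integer_, target_segments = NA_integer_)
  for (k in seq_len(n)) {
    new_block <- k > 1L && labels[k] != labels[k - 1L]
    if (new_block) {
      if (labels[k - 1L] == "rest") baseline <- compute_baseline(rest_buf)
      if (labels[k] == "rest") rest_buf <- numeric(0)
      block_onset <- k
    }
    if (labels[k] == "rest") {
      rest_buf <- c(rest_buf, raw[k])
    } else {
      lo <- if (window == "straddle") k - 2L else max(k - 2L, block_onset)
      win <- raw[max(lo, 1L):k]
      val <- mean(win)
      psc <- if (length(win) == 3L) compute_psc_nf(win, baseline)
             else (val - baseline) * 100 / baseline
      out$val[k] <- val
      out$baseline[k] <- baseline
      out$psc_nf[k] <- psc
      out$segments[k] <- map_to_segments(psc, psc_loc, protocol, rounding)
      out$target_segments[k] <- target_segments(labels[k], protocol)
    }
  }
  structure(out, calibration = calibration, region = calibration$region,
            design = design, class = c("feedback_trace", "data.frame"))
}

#' Mean online PSC over task volumes of one level
#'
#' @param trace A `"feedback_trace"` from [run_feedback_engine()].
#' @param level Task level label present in the trace (`"low"`, `"high"`, or
#'   `"task"` for a localizer).
#' @return Mean of `psc_nf` over all volumes of that level.
#' @export
online_mean_psc <- function(trace, level) {
  stopifnot(inherits(trace, "feedback_trace"))
  sel <- trace$block_type == level
  if (!any(sel))
    stop("level ", sQuote(level), " does not occur in this trace")
  mean(trace$psc_nf[sel])
}
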