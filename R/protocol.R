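#' Scan protocol parameters
#'
#' Bundles the acquisition and feedback-display constants of a graded
#' neurofeedback session: the repetition time (TR), the number of thermometer
#' segments, the fraction of the localizer percent signal change (PSC_LOC)
#' represented by one segment, and the two graded target levels expressed as
#' fractions of PSC_LOC.
#'
#' Defaults follow a 3T protocol with TR = 1.55 s and a 15-segment thermometer
#' in which each segment spans 10% of PSC_LOC; the *low* and *high* targets sit
#' at 50% and 100% of PSC_LOC (segments 5 and 10).
#'
#' @param tr_seconds Duration of one volume in seconds. Must be positive.
#' @param n_segments Number of thermometer segments (integer, >= 1).
#' @param segment_fraction Fraction of PSC_LOC represented by one segment,
#'   in (0, 1].
#' @param low_target_fraction,high_target_fraction Target levels as fractions
#'   of PSC_LOC; `0 < low < high` is required.
#' @return An object of class `"scan_protocol"`.
#' @examples
#' p <- scan_protocol()
#' p$tr_seconds
#' @export
scan_protocol <- function(tr_seconds = 1.55,
                          n_segments = 15L,
                          segment_fraction = 0.10,
                          low_target_fraction = 0.50,
                          high_target_fraction = 1.00) {
  stopifnot(is.numeric(tr_seconds), length(tr_seconds) == 1L, tr_seconds > 0)
  n_segments <- as.integer(n_segments)
  stopifnot(n_segments >= 1L)
  stopifnot(segment_fraction > 0, segment_fraction <= 1)
  stopifnot(low_target_fraction > 0,
            low_target_fraction < high_target_fraction)
  structure(
    list(tr_seconds = tr_seconds,
         n_segments = n_segments,
         segment_fraction = segment_fraction,
         low_target_fraction = low_target_fraction,
         high_target_fraction = high_target_fraction),
    class = "scan_protocol")
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat("Scan protocol: TR", x$tr_seconds, "s;",
      x$n_segments, "thermometer segments of",
      sprintf("%.0f%%", 100 * x$segment_fraction), "PSC_LOC;",
      "targets", sprintf("%.0f%%/%.0f%%", 100 * x$low_target_fraction,
                         100 * x$high_target_fraction), "\n")
  invisible(x)
}

## internal run-design constructor; no validation beyond tiling bookkeeping,
## so tests can build degenerate designs on purpose
new_run_design <- function(run_kind, block_type, n_volumes, protocol) {
  onset <- cumsum(c(0L, n_volumes[-length(n_volumes)]))
  blocks <- data.frame(block_type = block_type,
                       n_volumes = as.integer(n_volumes),
                       onset_volume = as.integer(onset),
                       stringsAsFactors = FALSE)
  structure(
    list(run_kind = run_kind,
         blocks = blocks,
         total_volumes = sum(blocks$n_volumes),
         level_order = blocks$block_type[blocks$block_type != "rest"],
         protocol = protocol),
    class = "run_design")
}

#' @export
print.run_design <- function(x, ...) {
  cat(sprintf("<run_design: %s, %d blocks, %d volumes (%.1f s)>\n",
              x$run_kind, nrow(x$blocks), x$total_volumes,
              x$total_volumes * x$protocol$tr_seconds))
  print(x$blocks, row.names = FALSE)
  invisible(x)
}

#' Build a neurofeedback run design
#'
#' A neurofeedback (NF) run is a rest/task tiling of 9 blocks of 20 volumes
#' each: five rest blocks flanking four task blocks, two at the *low* and two
#' at the *high* target level, for 180 volumes in total (279 s at TR 1.55 s).
#' Each block lasts `block_volumes * tr` seconds (31 s for the defaults).
#'
#' @param protocol A [scan_protocol()].
#' @param level_order Character vector of length 4 giving the target level of
#'   each task block in order; must contain `"low"` twice and `"high"` twice.
#' @param block_volumes Volumes per block (rest and task alike).
#' @return A `"run_design"` whose blocks tile the run without gaps.
#' @examples
#' d <- build_nf_run(scan_protocol(), c("low", "high", "low", "high"))
#' d$total_volumes  # 180
#' @export
build_nf_run <- function(protocol = scan_protocol(),
                         level_order = c("low", "high", "low", "high"),
                         block_volumes = 20L) {
  stopifnot(inherits(protocol, "scan_protocol"), block_volumes >= 1)
  bad <- setdiff(level_order, c("low", "high"))
  if (length(bad))
    stop("invalid target level label(s) in level_order: ",
         paste(sQuote(bad), collapse = ", "))
  if (length(level_order) != 4L ||
      sum(level_order == "low") != 2L || sum(level_order == "high") != 2L)
    stop("level_order must contain 'low' twice and 'high' twice; got {",
         paste(level_order, collapse = ", "), "}")
  types <- character(9L)
  types[seq(1L, 9L, by = 2L)] <- "rest"
  types[seq(2L, 8L, by = 2L)] <- level_order
  new_run_design("neurofeedback", types, rep(as.integer(block_volumes), 9L),
                 protocol)
}

#' Build a motor-execution localizer run design
#'
#' The localizer alternates rest and task blocks, rest first and last:
#' `n_task_blocks` task blocks flanked by `n_task_blocks + 1` rest blocks of
#' `block_volumes` volumes each. With the defaults (4 task blocks of 16
#' volumes at TR 1.55 s) every block lasts 24.8 s and the tiling spans 144
#' volumes. `pad_volumes` appends extra trailing rest volumes for protocols
#' whose total acquisition exceeds the block structure; the default is 0.
#'
#' @inheritParams build_nf_run
#' @param n_task_blocks Number of task blocks (>= 1).
#' @param block_volumes Volumes per block.
#' @param pad_volumes Extra rest volumes appended after the final rest block.
#' @return A `"run_design"`.
#' @examples
#' d <- build_localizer_run()
#' d$total_volumes                      # 144
#' 16 * scan_protocol()$tr_seconds      # 24.8 s per block
#' @export
build_localizer_run <- function(protocol = scan_protocol(),
                                n_task_blocks = 4L,
                                block_volumes = 16L,
                                pad_volumes = 0L) {
  stopifnot(inherits(protocol, "scan_protocol"),
            n_task_blocks >= 1, block_volumes >= 1, pad_volumes >= 0)
  n_blocks <- 2L * as.integer(n_task_blocks) + 1L
  types <- rep(c("rest", "task"), length.out = n_blocks)
  vols <- rep(as.integer(block_volumes), n_blocks)
  if (pad_volumes > 0) {
    types <- c(types, "rest")
    vols <- c(vols, as.integer(pad_volumes))
  }
  new_run_design("localizer", types, vols, protocol)
}

#' Counterbalanced session plans for a cohort
#'
#' Each subject's session comprises one localizer run followed by five NF runs
#' targeting one region and five targeting the other. The region order
#' alternates across consecutive subjects (subject 1 SMA-first, subject 2
#' M1-first, ...), and within each subject the task-level orders of the five
#' runs per region are drawn so that runs starting with *low* and with *high*
#' differ in count by at most one. Deterministic given `seed`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed for the level-order draw.
#' @param n_runs_per_region NF runs per target region (default 5).
#' @return A list of `"session_plan"` objects, one per subject, each holding
#'   `subject_id`, `region_order`, and a data frame `runs` with columns
#'   `run`, `target_region` and `level_order` (list column of length-4
#'   character vectors).
#' @export
assign_counterbalancing <- function(n_subjects, seed = 1L,
                                    n_runs_per_region = 5L) {
  stopifnot(n_subjects >= 1, n_runs_per_region >= 1)
  orders_low  <- list(c("low", "low", "high", "high"),
                      c("low", "high", "low", "high"),
                      c("low", "high", "high", "low"))
  orders_high <- lapply(orders_low, function(o)        # label-swapped mirror
    ifelse(o == "low", "high", "low"))
  rng <- local_rng(seed)
  lapply(seq_len(n_subjects), function(i) {
    region_order <- if (i %% 2L == 1L) c("SMA", "M1") else c("M1", "SMA")
    ## balanced first-level assignment: |#low-first - #high-first| <= 1 per
    ## region, and for odd run counts the majority first-level alternates
    ## between the two regions so it cancels within subject
    extra1 <- sample(c("low", "high"), 1L)
    plan_runs <- lapply(seq_along(region_order), function(ri) {
      n <- n_runs_per_region
      extra <- if (ri == 1L) extra1 else setdiff(c("low", "high"), extra1)
      firsts <- c(rep(c("low", "high"), n %/% 2L),
                  if (n %% 2L == 1L) extra)
      firsts <- sample(firsts)
      lapply(firsts, function(f) {
        pool <- if (f == "low") orders_low else orders_high
        pool[[sample.int(length(pool), 1L)]]
      })
    })
    runs <- data.frame(
      run = seq_len(2L * n_runs_per_region),
      target_region = rep(region_order, each = n_runs_per_region),
      stringsAsFactors = FALSE)
    runs$level_order <- c(plan_runs[[1]], plan_runs[[2]])
    structure(list(subject_id = i,
                   region_order = region_order,
                   runs = runs),
              class = "session_plan")
  })
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("<session_plan: subject %d, %s first, %d NF runs>\n",
              x$subject_id, x$region_order[1], nrow(x$runs)))
  invisible(x)
}

#' Write a run design as an events table
#'
#' Serializes a [build_nf_run()] / [build_localizer_run()] design as a
#' BIDS-style tab-separated events file with columns `onset` (seconds),
#' `duration` (seconds) and `trial_type`. Onsets are `onset_volume * TR`.
#'
#' @param design A `"run_design"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_events_tsv()] for the inverse.
#' @export
write_events_tsv <- function(design, path) {
  stopifnot(inherits(design, "run_design"))
  tr <- design$protocol$tr_seconds
  tab <- data.frame(
    onset = design$blocks$onset_volume * tr,
    duration = design$blocks$n_volumes * tr,
    trial_type = design$blocks$block_type,
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an events table back into a run design
#'
#' @param path Events TSV written by [write_events_tsv()].
#' @param protocol The [scan_protocol()] used when writing (supplies the TR).
#' @param run_kind `"neurofeedback"` or `"localizer"`; inferred from the
#'   trial types when `NULL`.
#' @return A `"run_design"`.
#' @export
read_events_tsv <- function(path, protocol = scan_protocol(),
                            run_kind = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(tab)))
  tr <- protocol$tr_seconds
  n_vol <- as.integer(round(tab$duration / tr))
  onset_vol <- as.integer(round(tab$onset / tr))
  if (any(abs(onset_vol - cumsum(c(0L, n_vol[-length(n_vol)]))) > 0))
    stop("events do not tile the run: onsets and durations disagree")
  if (is.null(run_kind))
    run_kind <- if ("task" %in% tab$trial_type) "localizer" else "neurofeedback"
  new_run_design(run_kind, tab$trial_type, n_vol, protocol)
}

## per-volume block-type labels for a design
volume_labels <- function(design) {
  rep(design$blocks$block_type, design$blocks$n_volumes)
}

## 0-based onset volumes of task (non-rest) blocks
task_onsets <- function(design) {
  b <- design$blocks
  b$onset_volume[b$block_type != "rest"]
}
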