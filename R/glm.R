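#' Design matrix for a neurofeedback run
#'
#' Columns: an intercept; a `task` regressor (HRF-convolved boxcar over all
#' four task blocks); a `level` parametric regressor coding `high = +1/2`,
#' `low = -1/2` on the same convolved support (so its coefficient is the
#' high-minus-low amplitude difference); and one unconvolved pre-onset
#' baseline indicator per task block spanning the last 10 volumes of the
#' preceding rest block, matching the online baseline window. No drift term
#' is included.
#'
#' @param design A neurofeedback `"run_design"`.
#' @param hrf Kernel from [make_hrf()]; built from the design's TR if `NULL`.
#' @param pre_onset_volumes Width of each pre-onset baseline window.
#' @return A numeric matrix with named columns and attributes `roles` (one of
#'   `"intercept"`, `"task"`, `"level"`, `"pre_onset"`, `"drift"` per column)
#'   and `design`.
#' @export
build_nf_design_matrix <- function(design, hrf = NULL,
                                   pre_onset_volumes = 10L) {
  stopifnot(inherits(design, "run_design"))
  if (is.null(hrf)) hrf <- make_hrf(design$protocol$tr_seconds)
  n <- design$total_volumes
  labels <- volume_labels(design)
  task_box <- as.numeric(labels != "rest")
  level_box <- ifelse(labels == "high", 0.5,
                      ifelse(labels == "low", -0.5, 0))
  onsets <- task_onsets(design)
  pre <- sapply(onsets, function(o) {
    col <- numeric(n)
    idx <- seq(o - pre_onset_volumes, o - 1L)  # 0-based volumes before onset
    if (any(idx < 0)) stop("pre-onset window extends before the run start")
    col[idx + 1L] <- 1
    col
  })
  colnames(pre) <- paste0("pre_onset_", seq_along(onsets))
  X <- cbind(intercept = 1,
             task = convolve_causal(task_box, hrf),
             level = convolve_causal(level_box, hrf),
             pre)
  roles <- c("intercept", "task", "level", rep("pre_onset", ncol(pre)))
  check_full_rank(X)
  structure(X, roles = roles, design = design)
}

#' Design matrix for a localizer run
#'
#' Columns: intercept, HRF-convolved task boxcar, and a mean-centred linear
#' drift term.
#'
#' @inheritParams build_nf_design_matrix
#' @return A numeric matrix with attributes `roles` and `design`.
#' @export
build_localizer_design_matrix <- function(design, hrf = NULL) {
  stopifnot(inherits(design, "run_design"))
  if (is.null(hrf)) hrf <- make_hrf(design$protocol$tr_seconds)
  n <- design$total_volumes
  task_box <- as.numeric(volume_labels(design) != "rest")
  drift <- seq_len(n) - 1
  drift <- drift - mean(drift)
  X <- cbind(intercept = 1,
             task = convolve_causal(task_box, hrf),
             drift = drift)
  check_full_rank(X)
  structure(X, roles = c("intercept", "task", "drift"), design = design)
}

check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  invisible(X)
}

#' Fit a GLM with AR(1) prewhitening
#'
#' Iterated Cochrane-Orcutt estimation. Starting from ordinary least squares,
#' each pass estimates the lag-1 autocorrelation of the current whitened
#' residuals, folds it into the AR(1) coefficient, whitens both the data and
#' the design matrix (first observation scaled by `sqrt(1 - rho^2)`,
#' subsequent observations quasi-differenced), and refits. At the fixed point
#' the whitened residuals are serially uncorrelated; a handful of passes
#' suffices, and a single correction pass already removes most of the
#' autocorrelation.
#'
#' @param series A `"roi_timeseries"` or numeric vector, length `nrow(X)`.
#' @param X Design matrix from [build_nf_design_matrix()] or
#'   [build_localizer_design_matrix()].
#' @param n_iter Number of whiten-and-refit passes (default 3).
#' @return An object of class `"nf_glm_fit"` with `betas`, `sigma2` (residual
#'   variance of the whitened fit), `ar1_rho_hat`, `dof`
#'   (`n_volumes - n_columns`), `residuals` (whitened) and the matrix's
#'   column `roles`.
#' @export
fit_glm_prewhitened <- function(series, X, n_iter = 3L) {
  y <- if (is.numeric(series)) series else series$signal
  if (length(y) != nrow(X))
    stop("series length (", length(y), ") does not match design matrix rows (",
         nrow(X), ")")
  stopifnot(n_iter >= 1)
  rho <- 0
  fit1 <- NULL
  for (pass in seq_len(n_iter + 1L)) {
    W <- function(z) {
      zm <- as.matrix(z)
      rbind(sqrt(1 - rho^2) * zm[1L, , drop = FALSE],
            zm[-1L, , drop = FALSE] - rho * zm[-nrow(zm), , drop = FALSE])
    }
    Xw <- W(X)
    colnames(Xw) <- colnames(X)
    fit1 <- stats::lm.fit(Xw, drop(W(y)))
    if (pass > n_iter) break
    e <- fit1$residuals
    delta <- if (sum(e^2) <= .Machine$double.eps * sum(y^2)) 0  # perfect fit
             else sum(e[-1] * e[-length(e)]) / sum(e^2)
    if (!is.finite(delta)) stop("AR(1) autocorrelation estimate undefined")
    rho <- rho + delta
    if (abs(rho) >= 1)
      stop("AR(1) residual autocorrelation estimate out of range: ", rho)
    if (abs(delta) < 1e-8) break
  }
  dof <- nrow(X) - ncol(X)
  structure(
    list(betas = fit1$coefficients,
         sigma2 = sum(fit1$residuals^2) / dof,
         ar1_rho_hat = rho,
         dof = dof,
         residuals = fit1$residuals,
         roles = attr(X, "roles")),
    class = "nf_glm_fit")
}

#' @export
print.nf_glm_fit <- function(x, ...) {
  cat(sprintf("<nf_glm_fit: %d coefficients, rho_hat = %.3f, dof = %d>\n",
              length(x$betas), x$ar1_rho_hat, x$dof))
  print(round(x$betas, 4))
  invisible(x)
}

#' Level-wise percent signal change from a neurofeedback GLM fit
#'
#' The offline PSC mirrors the online definition: the response amplitude of a
#' level is `task beta + 1/2 level beta` (high) or `task beta - 1/2 level
#' beta` (low); the baseline is the intercept plus the mean of the pre-onset
#' baseline coefficients, matching the online pre-onset window. PSC is the
#' response as a percentage of that baseline.
#'
#' @param fit An `"nf_glm_fit"` from a neurofeedback design.
#' @param X The design matrix used for the fit.
#' @param level `"low"` or `"high"`.
#' @return A one-row data frame of class `"psc_estimate"`: `level`, `psc`.
#' @export
extract_psc <- function(fit, X, level = c("high", "low")) {
  level <- match.arg(level)
  roles <- attr(X, "roles")
  if (!all(c("task", "level", "pre_onset") %in% roles))
    stop("fit does not come from a neurofeedback design matrix")
  b <- fit$betas
  baseline <- b[roles == "intercept"] + mean(b[roles == "pre_onset"])
  if (!is.finite(baseline) || baseline <= 0)
    stop("estimated baseline is non-positive (", baseline,
         "); cannot form percent signal change")
  resp <- b[roles == "task"] + (if (level == "high") 0.5 else -0.5) *
    b[roles == "level"]
  structure(data.frame(level = level,
                       psc = as.numeric(100 * resp / baseline)),
            class = c("psc_estimate", "data.frame"))
}

#' Localizer percent signal change
#'
#' For the localizer the baseline is simply the intercept:
#' `PSC_LOC = 100 * task beta / intercept beta`. With the plateau-normalized
#' HRF the task beta is the plateau amplitude of the block response.
#'
#' @param fit An `"nf_glm_fit"` from a localizer design.
#' @return Percent signal change (scalar).
#' @export
localizer_psc <- function(fit) {
  roles <- fit$roles
  if (!"task" %in% roles || "level" %in% roles)
    stop("fit does not come from a localizer design matrix")
  b <- fit$betas
  intercept <- b[roles == "intercept"]
  if (!is.finite(intercept) || intercept <= 0)
    stop("intercept is non-positive (", intercept,
         "); cannot form percent signal change")
  as.numeric(100 * b[roles == "task"] / intercept)
}

#' Event-related average around task-block onsets
#'
#' Averages the signal over a peri-onset window across all task blocks (and,
#' when a list of series is given, across runs and subjects), expressed as
#' percent change from each block's pre-onset baseline (mean of the 10
#' volumes before onset). With multiple subjects the error bars are
#' within-subject standard errors using the Cousineau-Morey subject-centering
#' correction.
#'
#' @param series A single `"roi_timeseries"`, a list of them (runs of one
#'   subject), or a list of such lists (subjects).
#' @param design The shared `"run_design"`.
#' @param window Integer vector `c(before, after)`: volumes before and after
#'   onset to include.
#' @return A data frame with `offset_volume`, `time_s`, `mean`, and (for >= 2
#'   subjects) `se_within`.
#' @export
event_related_average <- function(series, design, window = c(5L, 25L)) {
  stopifnot(inherits(design, "run_design"), length(window) == 2L,
            window[1] >= 0, window[2] >= 0)
  onsets <- task_onsets(design)
  n <- design$total_volumes
  offs <- seq(-window[1], window[2])
  if (min(onsets) - window[1] < 10L)
    stop("window extends before the first pre-onset baseline")
  if (max(onsets) + window[2] > n - 1L)
    stop("window extends past the end of the run")

  block_curves <- function(one) {
    raw <- if (is.numeric(one)) one else one$signal
    t(vapply(onsets, function(o) {
      base <- mean(raw[(o - 9L):o])  # 0-based volumes o-10..o-1 -> 1-based
      100 * (raw[o + offs + 1L] - base) / base
    }, numeric(length(offs))))
  }
  subject_curve <- function(runs) {
    if (!is.list(runs) || inherits(runs, "data.frame")) runs <- list(runs)
    colMeans(do.call(rbind, lapply(runs, block_curves)))
  }

  ## a list of lists is read as subjects x runs; anything else as one subject
  multi_subject <- is.list(series) && !is.data.frame(series) &&
    length(series) > 1L &&
    is.list(series[[1]]) && !is.data.frame(series[[1]])

  tr <- design$protocol$tr_seconds
  if (multi_subject) {
    mat <- do.call(rbind, lapply(series, subject_curve))  # subjects x time
    centred <- mat - rowMeans(mat) + mean(mat)            # Cousineau
    J <- ncol(mat)
    se <- apply(centred, 2, stats::sd) / sqrt(nrow(mat)) *
      sqrt(J / (J - 1))                                   # Morey correction
    data.frame(offset_volume = offs, time_s = offs * tr,
               mean = colMeans(mat), se_within = se)
  } else {
    data.frame(offset_volume = offs, time_s = offs * tr,
               mean = subject_curve(series))
  }
}
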