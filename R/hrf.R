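#' Canonical double-gamma hemodynamic response function
#'
#' Samples the canonical two-gamma hemodynamic response function (HRF) on the
#' TR grid: a positive gamma peaking around 5 s minus a scaled gamma modelling
#' the post-stimulus undershoot around 15 s.
#'
#' Normalization matters for calibration. With `normalize = "plateau"` (the
#' default) the sampled kernel is scaled to unit sum, so the response to a
#' sustained boxcar of amplitude *a* plateaus at exactly *a* once the kernel
#' is fully supported. This makes the simulated plateau percent signal change
#' equal the generative `psc_true`, which is what both the online thermometer
#' mapping and the offline percent-signal-change extraction assume.
#' `normalize = "peak"` scales the kernel to unit maximum instead.
#'
#' @param tr Sampling interval in seconds (the repetition time).
#' @param peak_delay,undershoot_delay Gamma delays in seconds (defaults 6 and
#'   16; the positive lobe's mode falls at `peak_delay - peak_dispersion`,
#'   i.e. 5 s).
#' @param peak_dispersion,undershoot_dispersion Gamma dispersions in seconds;
#'   must be positive.
#' @param undershoot_ratio Relative amplitude of the undershoot (default 1/6);
#'   0 gives a non-negative kernel.
#' @param duration Kernel length in seconds (default 32).
#' @param normalize `"plateau"` (unit sum) or `"peak"` (unit maximum).
#' @return Numeric vector of kernel weights on the TR grid, with attribute
#'   `"tr"`.
#' @examples
#' h <- make_hrf(tr = 1.55)
#' (which.max(h) - 1) * 1.55  # peak near 5 s
#' @export
make_hrf <- function(tr,
                     peak_delay = 6, undershoot_delay = 16,
                     peak_dispersion = 1, undershoot_dispersion = 1,
                     undershoot_ratio = 1 / 6,
                     duration = 32,
                     normalize = c("plateau", "peak")) {
  stopifnot(tr > 0, duration >= 20)
  if (peak_dispersion <= 0 || undershoot_dispersion <= 0)
    stop("HRF dispersions must be positive")
  normalize <- match.arg(normalize)
  t <- seq(0, duration, by = tr)
  h <- stats::dgamma(t, shape = peak_delay / peak_dispersion,
                     rate = 1 / peak_dispersion) -
    undershoot_ratio *
    stats::dgamma(t, shape = undershoot_delay / undershoot_dispersion,
                  rate = 1 / undershoot_dispersion)
  h <- switch(normalize,
              plateau = h / sum(h),
              peak = h / max(h))
  structure(h, tr = tr)
}
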