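## Seed handling -------------------------------------------------------------

## Set the RNG for the calling frame only: the global .Random.seed is restored
## when the caller exits, so library functions never disturb user RNG state.
local_rng <- function(seed, envir = parent.frame()) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  expr <- if (has_seed) {
    bquote(assign(".Random.seed", .(old), globalenv()))
  } else {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(seed)
}

#' Derive a child seed from a root seed
#'
#' Stages of the pipeline (cohort simulation, per-subject draws, physiological
#' traces, ...) each receive their own seed derived deterministically from a
#' single root seed, so any stage can be re-run in isolation and reproduce the
#' full-pipeline result. The fold keeps seeds inside the 32-bit integer range.
#'
#' @param seed Root integer seed.
#' @param ... One or more non-negative integer offsets identifying the stage
#'   (and, e.g., subject or run within the stage).
#' @return An integer seed.
#' @export
child_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in ks) s <- (s * 7919 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}

## round half away from zero (base round() is round-half-even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

## discrete causal convolution of a per-volume regressor with a kernel,
## truncated to the input length
convolve_causal <- function(x, kernel) {
  n <- length(x)
  stats::convolve(c(x, numeric(length(kernel))), rev(kernel),
                  type = "open")[seq_len(n)]
}

## stationary AR(1) series with marginal standard deviation `sd`
ar1_noise <- function(n, rho, sd) {
  stopifnot(abs(rho) < 1, sd >= 0, n >= 1)
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - rho^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1L, 0, sd)
  if (n > 1) {
    e <- stats::rnorm(n - 1L, 0, innov_sd)
    x <- stats::filter(c(x[1], e), rho, method = "recursive")
  }
  as.numeric(x)
}
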