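# Independent oracles used across test files. These deliberately re-derive
# results from scratch (naive per-volume recomputation, Riemann sums) so they
# share no code path with the implementation they check.

# Naive online-feedback oracle: for every task volume recompute the baseline
# and the 3-volume mean from the raw series alone, with no state carried
# between volumes.
naive_feedback <- function(raw, design, calibration,
                           rounding = c("nearest", "floor")) {
  rounding <- match.arg(rounding)
  protocol <- design$protocol
  labels <- rep(design$blocks$block_type, design$blocks$n_volumes)
  psc_loc <- calibration$psc_loc[[calibration$region]]
  blocks <- design$blocks
  out <- data.frame(volume = seq_along(raw) - 1L,
                    psc_nf = NA_real_, segments = NA_integer_)
  for (k in seq_along(raw)) {
    if (labels[k] == "rest") next
    # block containing volume k (0-based volume k-1)
    b <- max(which(blocks$onset_volume <= k - 1L))
    rb <- b - 1L  # preceding rest block
    stopifnot(blocks$block_type[rb] == "rest")
    rest_idx <- (blocks$onset_volume[rb] + blocks$n_volumes[rb] - 10L + 1L):
      (blocks$onset_volume[rb] + blocks$n_volumes[rb])  # 1-based
    baseline <- median(raw[rest_idx])
    val <- mean(raw[(k - 2L):k])
    psc <- (val - baseline) * 100 / baseline
    cont <- psc / (protocol$segment_fraction * psc_loc)
    seg <- if (rounding == "nearest") sign(cont) * floor(abs(cont) + 0.5)
           else floor(cont)
    out$psc_nf[k] <- psc
    out$segments[k] <- as.integer(min(max(seg, 0L), protocol$n_segments))
  }
  out
}

# Riemann-sum oracle for the informed half-normal Bayes factor.
riemann_bf <- function(t, n, scale, side, n_grid = 200000L) {
  df <- n - 1
  sgn <- if (side == "greater") 1 else -1
  hi <- 12 * scale
  delta <- (seq_len(n_grid) - 0.5) * hi / n_grid  # midpoint rule on (0, hi)
  dens <- dt(t, df = df, ncp = sgn * delta * sqrt(n)) *
    (2 / scale) * dnorm(delta / scale)
  sum(dens) * hi / n_grid / dt(t, df = df)
}

# Deterministic paired data with an exact target t statistic: differences
# with mean t/sqrt(n) and SD 1.
data_with_t <- function(t, n) {
  z <- seq_len(n)
  z <- (z - mean(z)) / sd(z)
  t / sqrt(n) + z
}

# Noiseless, drift-free generative parameters for closed-form checks.
noiseless_params <- function(psc_sma = c(task = 1, low = 0.5, high = 1),
                             psc_m1 = c(task = 1.48, low = -0.2, high = -0.2)) {
  subject_sim_params(psc_true = list(SMA = psc_sma, M1 = psc_m1),
                     noise_sd = 0, drift_slope = 0)
}

# 1-based indices of the last `k` volumes of every block with the given label.
plateau_index <- function(design, label, k = 5L) {
  b <- design$blocks
  unlist(lapply(which(b$block_type == label), function(i)
    (b$onset_volume[i] + b$n_volumes[i] - k + 1L):
      (b$onset_volume[i] + b$n_volumes[i])))
}
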