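# Independent oracles used across the suite. These deliberately avoid the
# package's own computation paths.

# magnitude of the 4th-order Butterworth band-pass at frequency f_hz:
# direct evaluation of signal::butter's transfer polynomial on the unit circle
bp_gain_oracle <- function(lo_hz, hi_hz, fs, f_hz) {
  ba <- signal::butter(2, c(lo_hz, hi_hz) * 2 / fs, type = "pass")
  z <- exp(-1i * 2 * pi * f_hz / fs)
  zp <- z^(seq_along(ba$b) - 1)
  Mod(sum(ba$b * zp) / sum(ba$a * zp))
}

# magnitude of the first-order DC blocker y[n] = g(x[n]-x[n-1]) + a y[n-1]
dc_gain_oracle <- function(cutoff_hz, fs, f_hz) {
  a <- exp(-2 * pi * cutoff_hz / fs)
  g <- (1 + a) / 2
  w <- 2 * pi * f_hz / fs
  g * Mod(1 - exp(-1i * w)) / Mod(1 - a * exp(-1i * w))
}

# steady-state amplitude of a sinusoidal response (peak over whole periods
# in the final stretch of the trace)
steady_amp <- function(y, fs, f_hz, periods = 20) {
  n <- length(y)
  k <- round(periods * fs / f_hz)
  max(abs(y[(n - k + 1):n]))
}

# brute-force per-sample comparator with no interlock
comparator_oracle <- function(env, threshold) {
  s <- 0L
  states <- integer(length(env))
  idx <- integer(0); dir <- integer(0)
  for (i in seq_along(env)) {
    if (s == 0L && env[i] >= threshold) {
      s <- 1L; idx <- c(idx, i); dir <- c(dir, 1L)
    } else if (s == 1L && env[i] < threshold) {
      s <- 0L; idx <- c(idx, i); dir <- c(dir, -1L)
    }
    states[i] <- s
  }
  list(states = states, idx = idx, dir = dir)
}

# Mann-Whitney pair statistic: fraction of correctly ordered
# positive-negative pairs, ties counted 1/2
pair_auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# average periodogram power in a band (smoothed periodogram, detrended)
band_power_oracle <- function(x, fs, lo, hi) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = 5,
                          plot = FALSE, detrend = TRUE, taper = 0.1)
  sel <- sp$freq >= lo & sp$freq <= hi
  mean(sp$spec[sel])
}

# slot index (1..48) of a wall-clock second, recomputed independently
slot_oracle <- function(clock_s) floor((clock_s %% 86400) / 1800) + 1
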