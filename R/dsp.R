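#' Signal-chain configuration
#'
#' Parameters of the device's embedded signal-conditioning chain: a
#' first-order IIR offset remover, a fourth-order IIR band-pass (Butterworth,
#' run as two cascaded biquads), a rectifier and an exponential-moving-average
#' envelope smoother, plus the recorder's amplitude quantisation step.
#'
#' @param band_lo_hz,band_hi_hz band-pass edges in Hz. Canonical bands:
#'   beta 13–30, seizure 10–20, gamma 55–65, theta-alpha 5–10.
#' @param offset_cutoff_hz corner frequency of the offset-removal high-pass,
#'   Hz. Default 0.5, well below the lowest band edge in use.
#' @param ema_tau_s envelope smoothing time constant, seconds. The EMA
#'   coefficient is `alpha = 1 - exp(-1/(fs * ema_tau_s))`, so the time
#'   constant is sampling-rate independent.
#' @param bp_order band-pass order; the device chain is fixed at 4.
#' @param quant_uv amplitude quantisation step of the stored envelope,
#'   microvolts (device resolution ~1 uV).
#' @return An object of class `chain_config`.
#' @examples
#' chain_config(13, 30)           # beta band
#' chain_config(10, 20, ema_tau_s = 1)  # seizure band
#' @export
chain_config <- function(band_lo_hz, band_hi_hz, offset_cutoff_hz = 0.5,
                         ema_tau_s = 0.5, bp_order = 4, quant_uv = 1) {
  stopifnot(is.numeric(band_lo_hz), is.numeric(band_hi_hz))
  if (bp_order != 4) stop("the device band-pass order is fixed at 4")
  if (!(offset_cutoff_hz > 0 && offset_cutoff_hz < band_lo_hz &&
        band_lo_hz < band_hi_hz)) {
    stop("need 0 < offset_cutoff_hz < band_lo_hz < band_hi_hz")
  }
  if (ema_tau_s <= 0) stop("'ema_tau_s' must be positive")
  if (quant_uv <= 0) stop("'quant_uv' must be positive")
  structure(list(band_lo_hz = band_lo_hz, band_hi_hz = band_hi_hz,
                 offset_cutoff_hz = offset_cutoff_hz, ema_tau_s = ema_tau_s,
                 bp_order = 4, quant_uv = quant_uv),
            class = "chain_config")
}

#' @export
print.chain_config <- function(x, ...) {
  cat(sprintf(paste0("<chain_config> band %g-%g Hz, offset cutoff %g Hz, ",
                     "ema tau %g s, quant %g uV\n"),
              x$band_lo_hz, x$band_hi_hz, x$offset_cutoff_hz,
              x$ema_tau_s, x$quant_uv))
  invisible(x)
}

# Fourth-order Butterworth band-pass as two second-order sections.
# Coefficients come from signal::butter; the direct-form polynomial is
# factored into biquads (poles paired by conjugacy, band-pass zeros at +-1
# split one pair per section) for numerically stable narrow-band operation.
butter_sos <- function(lo_hz, hi_hz, fs) {
  if (hi_hz >= fs / 2) {
    stop(sprintf("band_hi_hz (%g) must be below the Nyquist rate (%g)",
                 hi_hz, fs / 2))
  }
  if (lo_hz <= 0) stop("band_lo_hz must be positive")
  ba <- signal::butter(2, c(lo_hz, hi_hz) * 2 / fs, type = "pass")
  b <- ba$b; a <- ba$a
  p <- polyroot(rev(a))                       # 4 poles, two conjugate pairs
  p <- p[order(Im(p))]
  pairs <- list(c(p[1L], p[4L]), c(p[2L], p[3L]))  # conjugates together
  k <- b[1L]                                  # overall gain; zeros at +-1
  g <- sqrt(abs(k)) * sign(k)^c(1, 1)
  sos <- matrix(0, nrow = 2, ncol = 6)
  for (i in 1:2) {
    pp <- pairs[[i]]
    sos[i, ] <- c(g[i] * c(1, 0, -1),          # (z-1)(z+1) = z^2 - 1
                  1, -Re(pp[1L] + pp[2L]), Re(pp[1L] * pp[2L]))
  }
  sos
}

dc_coef <- function(cutoff_hz, fs) exp(-2 * pi * cutoff_hz / fs)

ema_alpha <- function(tau_s, fs) 1 - exp(-1 / (fs * tau_s))

#' Remove channel offset (first-order IIR high-pass)
#'
#' Emulates step 1 of the embedded chain: a first-order IIR DC blocker
#' `y[n] = g (x[n] - x[n-1]) + a y[n-1]` with `a = exp(-2 pi fc / fs)` and
#' `g = (1 + a)/2`, giving zero DC gain and near-unity gain well above the
#' cutoff.
#'
#' @param x a [raw_signal()].
#' @param cfg a [chain_config()] (only `offset_cutoff_hz` is used), or a
#'   numeric cutoff in Hz.
#' @return a [raw_signal()] of the same length and rate.
#' @export
remove_offset <- function(x, cfg = 0.5) {
  stopifnot(inherits(x, "raw_signal"))
  fc <- if (inherits(cfg, "chain_config")) cfg$offset_cutoff_hz else cfg
  if (fc <= 0 || fc >= x$fs / 2) stop("offset cutoff must be in (0, fs/2)")
  raw_signal(dc_blocker_cpp(x$samples, dc_coef(fc, x$fs)), x$fs, x$t0)
}

#' Band-pass filter (fourth-order IIR, causal)
#'
#' Step 2 of the chain: a fourth-order Butterworth band-pass applied as two
#' cascaded biquads, single pass (the device runs in real time, so no
#' zero-phase filtering).
#'
#' @param x a [raw_signal()].
#' @param cfg a [chain_config()] giving the band edges.
#' @return a [raw_signal()] of the same length and rate.
#' @export
bandpass <- function(x, cfg) {
  stopifnot(inherits(x, "raw_signal"), inherits(cfg, "chain_config"))
  sos <- butter_sos(cfg$band_lo_hz, cfg$band_hi_hz, x$fs)
  raw_signal(sos_filter_cpp(x$samples, sos), x$fs, x$t0)
}

#' Rectify a signal
#'
#' Step 3 of the chain: elementwise absolute value, producing a noisy
#' envelope of the band-passed signal. Idempotent.
#'
#' @param x a [raw_signal()].
#' @return a [raw_signal()] with non-negative samples.
#' @export
rectify <- function(x) {
  stopifnot(inherits(x, "raw_signal"))
  raw_signal(abs(x$samples), x$fs, x$t0)
}

#' Envelope smoothing by exponential moving average
#'
#' Step 4 of the chain: `y[n] = alpha x[n] + (1 - alpha) y[n-1]` with
#' `alpha = 1 - exp(-1/(fs tau))`, i.e. a one-pole low-pass with unity DC
#' gain and time constant `tau` seconds.
#'
#' @param x a [raw_signal()] (typically rectified).
#' @param ema_tau_s smoothing time constant in seconds.
#' @return an [envelope_signal()] at the input rate.
#' @export
ema_smooth <- function(x, ema_tau_s = 0.5) {
  stopifnot(inherits(x, "raw_signal"))
  if (ema_tau_s <= 0) stop("'ema_tau_s' must be positive")
  y <- ema_cpp(x$samples, ema_alpha(ema_tau_s, x$fs))
  envelope_signal(pmax(y, 0), x$fs, x$t0)
}

#' Power-in-band envelope (full signal chain)
#'
#' Runs the complete embedded chain: offset removal, band-pass,
#' rectification, EMA smoothing, with optional quantisation of the output to
#' `quant_uv` steps (round half away from zero), matching the recorder's
#' ~1 uV resolution. Quantisation is opt-in so that sub-microvolt analytic
#' checks of the chain remain exact.
#'
#' @param x a [raw_signal()].
#' @param cfg a [chain_config()].
#' @param quantize quantise the output envelope to `cfg$quant_uv` steps.
#' @return an [envelope_signal()] at the input rate.
#' @examples
#' x <- raw_signal(100 * sin(2 * pi * 20 * (0:6299) / 630), fs = 630)
#' env <- power_in_band(x, chain_config(13, 30))
#' tail(env$values, 1)  # ~ 100 * 2/pi
#' @export
power_in_band <- function(x, cfg, quantize = FALSE) {
  stopifnot(inherits(x, "raw_signal"), inherits(cfg, "chain_config"))
  env <- ema_smooth(rectify(bandpass(remove_offset(x, cfg), cfg)),
                    cfg$ema_tau_s)
  if (quantize) env$values <- quantize_uv(env$values, cfg$quant_uv)
  env
}

#' Quantise amplitudes to a step size
#'
#' Round half away from zero to integer multiples of `step` (the recorder's
#' amplitude resolution).
#'
#' @param v numeric vector.
#' @param step quantisation step (default 1 uV).
#' @return numeric vector of multiples of `step`.
#' @export
quantize_uv <- function(v, step = 1) {
  sign(v) * floor(abs(v) / step + 0.5) * step
}

#' Accelerometer motion-magnitude pipeline
#'
#' Combines triaxial acceleration into an overall motion signal: per-sample
#' Euclidean magnitude (square, sum, square root), fourth-order Butterworth
#' low-pass at 5 Hz to attenuate collision spikes, then normalisation to the
#' session peak. An all-zero session skips normalisation and returns zeros.
#'
#' @param ax,ay,az equal-length acceleration streams in g.
#' @param fs sampling rate, Hz (default 100).
#' @param lp_cutoff_hz low-pass cutoff, Hz.
#' @param t0 wall-clock start time.
#' @return a [motion_signal()] with values in \[0, 1\].
#' @export
motion_magnitude <- function(ax, ay, az, fs = 100, lp_cutoff_hz = 5,
                             t0 = "00:00:00") {
  if (length(ax) != length(ay) || length(ay) != length(az)) {
    stop("the three acceleration streams must have equal length")
  }
  mag <- sqrt(ax^2 + ay^2 + az^2)
  lp <- signal::butter(4, lp_cutoff_hz * 2 / fs, type = "low")
  # pad with the first value so the session peak is never the filter's own
  # onset transient
  npad <- round(10 * fs / lp_cutoff_hz)
  sm <- as.numeric(signal::filter(lp, c(rep(mag[1L], npad), mag)))
  sm <- pmax(sm[(npad + 1L):length(sm)], 0)
  peak <- max(sm)
  if (peak > 0) sm <- sm / peak
  motion_signal(pmin(sm, 1), fs, t0)
}
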