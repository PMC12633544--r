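#' Single-channel biopotential trace
#'
#' Container for a uniformly sampled single-channel biopotential signal
#' (LFP/ECoG-like), in microvolts, with its sampling rate and wall-clock
#' start time. This is the common currency of the simulator: generators
#' produce it, the signal chain consumes it, and the file readers return it.
#'
#' @param samples numeric vector of amplitudes in microvolts; must be finite.
#' @param fs sampling rate in Hz (device default 630).
#' @param t0 wall-clock start time, `"HH:MM:SS"` (or `"HH:MM"`).
#' @return An object of class `raw_signal`: a list with elements `samples`,
#'   `fs` and `t0`.
#' @examples
#' x <- raw_signal(sin(2 * pi * 20 * seq(0, 1, by = 1 / 630)), fs = 630)
#' x
#' @export
raw_signal <- function(samples, fs = 630, t0 = "00:00:00") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("'samples' must have length >= 1")
  bad <- which(!is.finite(samples))
  if (length(bad)) {
    stop(sprintf("non-finite sample at index %d (first of %d)",
                 bad[1L], length(bad)))
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a single positive number")
  }
  parse_clock(t0)  # validates
  structure(list(samples = samples, fs = fs, t0 = t0),
            class = "raw_signal")
}

#' Power-in-band envelope trace
#'
#' Non-negative envelope amplitudes in microvolts, as produced by
#' [power_in_band()] or [ema_smooth()]. `fs_env` may be lower than the
#' source rate when the envelope has been decimated for recording.
#'
#' @param values non-negative numeric vector, microvolts.
#' @param fs_env sampling rate of the envelope in Hz.
#' @param t0 wall-clock start time, `"HH:MM:SS"`.
#' @return An object of class `envelope_signal`.
#' @export
envelope_signal <- function(values, fs_env, t0 = "00:00:00") {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("envelope values must be finite")
  if (any(values < 0)) stop("envelope values must be non-negative")
  if (fs_env <= 0) stop("'fs_env' must be positive")
  parse_clock(t0)
  structure(list(values = values, fs_env = fs_env, t0 = t0),
            class = "envelope_signal")
}

#' Normalised motion-magnitude trace
#'
#' Output of the accelerometer pipeline ([motion_magnitude()]): per-sample
#' Euclidean acceleration magnitude, low-pass filtered and normalised to the
#' session peak, so all values lie in \[0, 1\].
#'
#' @param values numeric vector in \[0, 1\].
#' @param fs sampling rate in Hz (accelerometer default 100).
#' @param t0 wall-clock start time.
#' @return An object of class `motion_signal`.
#' @export
motion_signal <- function(values, fs = 100, t0 = "00:00:00") {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("motion values must be finite")
  if (any(values < 0 | values > 1)) stop("motion values must lie in [0, 1]")
  if (fs <= 0) stop("'fs' must be positive")
  parse_clock(t0)
  structure(list(values = values, fs = fs, t0 = t0),
            class = "motion_signal")
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("<raw_signal> %d samples @ %g Hz (%.2f s), t0 %s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$t0))
  cat(sprintf("  range [%.2f, %.2f] uV, rms %.2f uV\n",
              min(x$samples), max(x$samples), sqrt(mean(x$samples^2))))
  invisible(x)
}

#' @export
print.envelope_signal <- function(x, ...) {
  cat(sprintf("<envelope_signal> %d samples @ %g Hz, t0 %s, max %.2f uV\n",
              length(x$values), x$fs_env, x$t0, max(x$values)))
  invisible(x)
}

#' @export
print.motion_signal <- function(x, ...) {
  cat(sprintf("<motion_signal> %d samples @ %g Hz, t0 %s\n",
              length(x$values), x$fs, x$t0))
  invisible(x)
}

#' Parse a wall-clock time to seconds since midnight
#'
#' @param t0 `"HH:MM:SS"` or `"HH:MM"` string (24-h clock), or a single
#'   numeric already in seconds.
#' @return seconds since midnight (numeric scalar in \[0, 86400)).
#' @export
parse_clock <- function(t0) {
  if (is.numeric(t0) && length(t0) == 1L && is.finite(t0)) {
    return(t0 %% 86400)
  }
  if (!is.character(t0) || length(t0) != 1L ||
      !grepl("^\\d{1,2}:\\d{2}(:\\d{2})?$", t0)) {
    stop(sprintf("malformed clock time: %s", deparse(substitute(t0))),
         call. = FALSE)
  }
  parts <- as.numeric(strsplit(t0, ":", fixed = TRUE)[[1L]])
  if (length(parts) == 2L) parts <- c(parts, 0)
  if (parts[1L] > 24 || parts[2L] >= 60 || parts[3L] >= 60) {
    stop(sprintf("malformed clock time: %s", t0), call. = FALSE)
  }
  (parts[1L] * 3600 + parts[2L] * 60 + parts[3L]) %% 86400
}

#' Format seconds since midnight as HH:MM:SS
#' @param s seconds since midnight.
#' @return character string `"HH:MM:SS"`.
#' @export
format_clock <- function(s) {
  s <- round(s %% 86400)
  sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
}

signal_duration <- function(x) {
  if (inherits(x, "envelope_signal")) length(x$values) / x$fs_env
  else length(x$samples %||% x$values) / x$fs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
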