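#' Debounced threshold-classifier configuration
#'
#' Single-threshold comparator with a timing interlock ("debounce"): after
#' any state change the state is held for at least `debounce_s` seconds.
#' The device study range for the debounce is 10–120 s; values outside are
#' allowed with a warning.
#'
#' @param threshold_uv envelope threshold in microvolts (for `source =
#'   "motion"` the threshold is on the normalised 0–1 motion scale).
#' @param debounce_s minimum dwell time in any state, seconds.
#' @param source which stream is classified, `"envelope"` or `"motion"`.
#' @return An object of class `classifier_config`.
#' @examples
#' classifier_config(80, debounce_s = 10)           # nighttime gamma classifier
#' classifier_config(0.3, 30, source = "motion")    # motion trigger
#' @export
classifier_config <- function(threshold_uv, debounce_s = 10,
                              source = c("envelope", "motion")) {
  source <- match.arg(source)
  if (threshold_uv <= 0) stop("'threshold_uv' must be positive")
  if (debounce_s < 0) stop("'debounce_s' must be non-negative")
  if (debounce_s > 0 && (debounce_s < 10 || debounce_s > 120)) {
    warning(sprintf("debounce %g s is outside the device study range [10, 120] s",
                    debounce_s))
  }
  structure(list(threshold_uv = threshold_uv, debounce_s = debounce_s,
                 source = source),
            class = "classifier_config")
}

#' Stimulation control policy
#'
#' Constant-current pulse-train policy: a baseline amplitude while the
#' classifier is LOW, a triggered amplitude while HIGH, with amplitude
#' changes ramped at `ramp_ma_per_pulse` per pulse (device value 0.01
#' mA/pulse). `baseline_freq_hz` allows a different pulse frequency at
#' baseline than when triggered (e.g. 6 Hz baseline with 126 Hz adaptive
#' switches in the epilepsy bench). With `sham = TRUE` triggers are logged
#' but the delivered amplitude stays at baseline.
#'
#' @param baseline_ma baseline current, mA.
#' @param active_ma triggered current, mA. Amplitudes above the 4.0 mA
#'   device bound are allowed with a warning.
#' @param freq_hz pulse frequency while triggered, Hz (device 126).
#' @param pw_us pulse width, microseconds.
#' @param ramp_ma_per_pulse ramp increment per pulse, mA.
#' @param baseline_freq_hz pulse frequency at baseline; defaults to `freq_hz`.
#' @param sham if `TRUE`, log triggers but do not raise the amplitude.
#' @return An object of class `stim_policy`.
#' @examples
#' stim_policy(0.1, 4.0)                       # aDBS ramp 0.1 -> 4.0 mA
#' stim_policy(1, 4, baseline_freq_hz = 6)     # 6 Hz baseline, 126 Hz adaptive
#' @export
stim_policy <- function(baseline_ma = 0.1, active_ma = 4.0, freq_hz = 126,
                        pw_us = 100, ramp_ma_per_pulse = 0.01,
                        baseline_freq_hz = freq_hz, sham = FALSE) {
  if (baseline_ma < 0 || active_ma < baseline_ma) {
    stop("need 0 <= baseline_ma <= active_ma")
  }
  if (active_ma > 4.0) {
    warning(sprintf("active_ma %g mA exceeds the 4.0 mA device bound", active_ma))
  }
  if (freq_hz <= 0 || baseline_freq_hz <= 0) stop("pulse frequencies must be positive")
  if (ramp_ma_per_pulse <= 0) stop("'ramp_ma_per_pulse' must be positive")
  structure(list(baseline_ma = baseline_ma, active_ma = active_ma,
                 freq_hz = freq_hz, pw_us = pw_us,
                 ramp_ma_per_pulse = ramp_ma_per_pulse,
                 baseline_freq_hz = baseline_freq_hz, sham = isTRUE(sham)),
            class = "stim_policy")
}

make_state_trace <- function(states, idx, dir, fs, t0 = "00:00:00",
                             debounce_s = 0) {
  transitions <- data.frame(
    time_s = idx / fs,
    direction = ifelse(dir > 0, "low_to_high", "high_to_low"),
    stringsAsFactors = FALSE
  )
  structure(list(states = states, fs = fs, t0 = t0,
                 transitions = transitions,
                 crossings = sum(dir > 0), debounce_s = debounce_s),
            class = "state_trace")
}

#' @export
print.state_trace <- function(x, ...) {
  cat(sprintf("<state_trace> %d samples @ %g Hz, %d transitions (%d crossings)\n",
              length(x$states), x$fs, nrow(x$transitions), x$crossings))
  invisible(x)
}

#' Debounced threshold classification of an envelope
#'
#' The state starts LOW and flips to HIGH at the first sample at or above
#' the threshold, back to LOW at the first sample below it, except that
#' after any flip the state is locked for `debounce_s` seconds (symmetric
#' interlock; re-crossings during the lock neither retrigger nor extend it).
#'
#' @param env an [envelope_signal()].
#' @param cfg a [classifier_config()].
#' @return A `state_trace`: per-sample binary states, a `transitions`
#'   data frame (`time_s`, `direction`), and the LOW-to-HIGH `crossings`
#'   count (the quantity the device logs per half-hour slot).
#' @examples
#' env <- envelope_signal(c(rep(0, 10), rep(100, 10), rep(0, 20)), fs_env = 1)
#' threshold_classify(env, classifier_config(80, debounce_s = 10))
#' @export
threshold_classify <- function(env, cfg) {
  stopifnot(inherits(env, "envelope_signal"), inherits(cfg, "classifier_config"))
  res <- classify_cpp(env$values, env$fs_env, cfg$threshold_uv, cfg$debounce_s)
  make_state_trace(res$states, res$idx, res$dir, env$fs_env, env$t0,
                   cfg$debounce_s)
}

#' Debounced trigger on the motion stream
#'
#' Same semantics as [threshold_classify()], applied to the normalised
#' motion magnitude (threshold on the 0–1 scale).
#'
#' @param m a [motion_signal()].
#' @param cfg a [classifier_config()] with `source = "motion"`.
#' @return a `state_trace`.
#' @export
motion_trigger <- function(m, cfg) {
  stopifnot(inherits(m, "motion_signal"), inherits(cfg, "classifier_config"))
  if (cfg$source != "motion") {
    stop("motion_trigger requires a classifier_config with source = 'motion'")
  }
  res <- classify_cpp(m$values, m$fs, cfg$threshold_uv, cfg$debounce_s)
  make_state_trace(res$states, res$idx, res$dir, m$fs, m$t0, cfg$debounce_s)
}

#' Ramped stimulation amplitude from a state trace
#'
#' Emulates the constant-current engine: a continuous pulse train whose
#' amplitude moves towards the active (HIGH) or baseline (LOW) level by at
#' most `ramp_ma_per_pulse` at each pulse instant. Ramp-down uses the same
#' per-pulse rate. Under `sham` the amplitude stays at baseline but states
#' and crossing counts are unchanged.
#'
#' @param states a `state_trace` from [threshold_classify()] or
#'   [motion_trigger()].
#' @param pol a [stim_policy()].
#' @param amp0 initial amplitude, mA (defaults to the baseline).
#' @param keep_pulses also return per-pulse times and amplitudes (can be
#'   large for long sessions).
#' @return An `amplitude_trace`: `amplitude_ma` per state sample, plus
#'   `pulse_times_s`/`pulse_amps_ma` when requested.
#' @examples
#' st <- threshold_classify(
#'   envelope_signal(c(rep(0, 63), rep(100, 630 * 4)), fs_env = 630),
#'   classifier_config(80, debounce_s = 0))
#' amp <- ramp_stimulation(st, stim_policy(0.1, 4.0), keep_pulses = TRUE)
#' max(amp$amplitude_ma)  # reaches 4.0 after 390 pulses
#' @export
ramp_stimulation <- function(states, pol, amp0 = pol$baseline_ma,
                             keep_pulses = FALSE) {
  stopifnot(inherits(states, "state_trace"), inherits(pol, "stim_policy"))
  res <- ramp_cpp(states$states, states$fs, pol$baseline_ma, pol$active_ma,
                  pol$ramp_ma_per_pulse, pol$freq_hz, pol$baseline_freq_hz,
                  amp0, pol$sham, keep_pulses)
  out <- list(amplitude_ma = res$amplitude_ma, fs = states$fs, t0 = states$t0,
              policy = pol, crossings = states$crossings)
  if (keep_pulses) {
    out$pulse_times_s <- res$pulse_times_s
    out$pulse_amps_ma <- res$pulse_amps_ma
  }
  structure(out, class = "amplitude_trace")
}

#' @export
print.amplitude_trace <- function(x, ...) {
  cat(sprintf("<amplitude_trace> %d samples @ %g Hz, range [%.2f, %.2f] mA\n",
              length(x$amplitude_ma), x$fs,
              min(x$amplitude_ma), max(x$amplitude_ma)))
  invisible(x)
}

#' Maximum deliverable current under the compliance voltage
#'
#' The stimulation engine has a +-15 V compliance voltage and a 4.0 mA
#' programmable maximum; into an electrode impedance `R` kOhm the
#' deliverable current is `min(4, 15 / R)` mA. Electrode impedances are
#' restricted to below 4 kOhm in the device.
#'
#' @param impedance_kohm electrode impedance in kOhm (> 0).
#' @return maximum deliverable current in mA.
#' @examples
#' max_deliverable_current(1.5)  # 4.0 (device-limited)
#' max_deliverable_current(4.0)  # 3.75 (compliance-limited)
#' @export
max_deliverable_current <- function(impedance_kohm) {
  if (any(impedance_kohm <= 0)) stop("'impedance_kohm' must be positive")
  pmin(4.0, 15 / impedance_kohm)
}
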