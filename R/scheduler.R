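#' Device configuration profile
#'
#' One complete device configuration, selectable by the circadian scheduler:
#' sensing montage, signal-chain parameters, classifier and control policy.
#' Within a profile, stimulation contacts cannot also be used for sensing
#' (device rule).
#'
#' @param id profile identifier, `"A"` or `"B"`.
#' @param chain a [chain_config()].
#' @param classifier a [classifier_config()].
#' @param policy a [stim_policy()].
#' @param sense_contacts,stim_contacts integer contact ids (eight contacts,
#'   1–8, on the device).
#' @return An object of class `stim_profile`.
#' @examples
#' pd_day <- stim_profile("A", chain_config(13, 30),
#'                        classifier_config(12, 10),
#'                        stim_policy(0.5, 3, freq_hz = 126, pw_us = 90),
#'                        sense_contacts = c(1, 2), stim_contacts = c(3, 4))
#' validate_profile(pd_day)
#' @export
stim_profile <- function(id, chain, classifier, policy,
                         sense_contacts = c(1L, 2L),
                         stim_contacts = c(3L, 4L)) {
  stopifnot(inherits(chain, "chain_config"),
            inherits(classifier, "classifier_config"),
            inherits(policy, "stim_policy"))
  structure(list(id = as.character(id), chain = chain,
                 classifier = classifier, policy = policy,
                 sense_contacts = as.integer(sense_contacts),
                 stim_contacts = as.integer(stim_contacts)),
            class = "stim_profile")
}

#' Validate a profile against the device rules
#'
#' Checks contact disjointness (stimulation electrodes cannot be used for
#' sensing within the same scheduler epoch), band validity for the device
#' sampling rate, and the soft amplitude bound (4.0 mA).
#'
#' @param p a [stim_profile()].
#' @param fs device sampling rate used for the band validity check.
#' @return Character vector of violation messages; empty if the profile is
#'   valid. Soft-bound breaches are prefixed `"warning:"`.
#' @export
validate_profile <- function(p, fs = 630) {
  stopifnot(inherits(p, "stim_profile"))
  v <- character(0)
  shared <- intersect(p$sense_contacts, p$stim_contacts)
  if (length(shared)) {
    v <- c(v, sprintf("contacts %s are in both the sensing and stimulation montage",
                      paste(shared, collapse = ", ")))
  }
  if (p$chain$band_hi_hz >= fs / 2) {
    v <- c(v, sprintf("band_hi_hz %g is not below the Nyquist rate %g",
                      p$chain$band_hi_hz, fs / 2))
  }
  if (p$policy$active_ma > 4.0) {
    v <- c(v, sprintf("warning: active_ma %g mA exceeds the 4.0 mA device bound",
                      p$policy$active_ma))
  }
  if (p$policy$baseline_ma > 4.0) {
    v <- c(v, sprintf("warning: baseline_ma %g mA exceeds the 4.0 mA device bound",
                      p$policy$baseline_ma))
  }
  v
}

#' 48-slot circadian schedule
#'
#' Maps each half-hour slot of the 24-h day (half-open intervals
#' `[start, start + 30 min)`) to a profile id. In strict device-parity mode
#' at most two distinct profiles are allowed; `research = TRUE` lifts the
#' cap (with a message, since the device itself cannot do this).
#'
#' @param slots character vector of 48 profile ids covering 00:00–24:00.
#' @param profiles named list of [stim_profile()] objects keyed by id.
#' @param research allow more than two distinct profiles.
#' @return An object of class `device_schedule`.
#' @seealso [schedule_day_night()] for the common two-profile layout.
#' @export
device_schedule <- function(slots, profiles, research = FALSE) {
  slots <- as.character(slots)
  if (length(slots) != 48L) stop("a schedule has exactly 48 half-hour slots")
  ids <- unique(slots)
  if (length(ids) > 2L && !research) {
    stop("strict device-parity mode allows at most 2 distinct profiles; ",
         "set research = TRUE to lift the cap")
  }
  if (length(ids) > 2L) message("research mode: schedule uses ",
                                length(ids), " profiles (device limit is 2)")
  missing_ids <- setdiff(ids, names(profiles))
  if (length(missing_ids)) {
    bad_slot <- which(slots == missing_ids[1L])[1L]
    stop(sprintf("slot %d (%s) references undefined profile '%s'",
                 bad_slot, format_clock((bad_slot - 1) * 1800), missing_ids[1L]))
  }
  for (p in profiles) stopifnot(inherits(p, "stim_profile"))
  structure(list(slots = slots, profiles = profiles),
            class = "device_schedule")
}

#' Build a day/night two-profile schedule
#'
#' @param day,night [stim_profile()] objects for the two phases.
#' @param day_start,day_end wall-clock boundaries of the day phase
#'   (half-open; the night profile is active on `[day_end, day_start)`).
#' @return a [device_schedule()].
#' @examples
#' # daytime beta-adaptive 06:00-22:00, nighttime motion-adaptive otherwise
#' @export
schedule_day_night <- function(day, night, day_start = "06:00",
                               day_end = "22:00") {
  s0 <- parse_clock(day_start) / 1800
  s1 <- parse_clock(day_end) / 1800
  if (s0 %% 1 != 0 || s1 %% 1 != 0) {
    stop("schedule boundaries must fall on half-hour marks")
  }
  idx <- seq_len(48L) - 1L
  in_day <- if (s0 <= s1) idx >= s0 & idx < s1 else idx >= s0 | idx < s1
  slots <- ifelse(in_day, day$id, night$id)
  profs <- stats::setNames(list(day, night), c(day$id, night$id))
  device_schedule(slots, profs)
}

#' Profile active at a clock time
#'
#' @param clock_time `"HH:MM:SS"` string or seconds since midnight.
#' @param schedule a [device_schedule()].
#' @return The active profile id (slot intervals are half-open, so 22:00:00
#'   already belongs to the 22:00–22:30 slot).
#' @export
active_profile <- function(clock_time, schedule) {
  stopifnot(inherits(schedule, "device_schedule"))
  s <- parse_clock(clock_time)
  schedule$slots[[floor(s / 1800) + 1L]]
}

#' Loop-recorder configuration
#'
#' The device's circular ("loop") recorder: a 128 kB buffer of 16-bit
#' samples filled at the base rate divided by a power-of-two decimation
#' factor (each stored value is the mean of its decimation block). The
#' 16-bit word size is an inference from the printed capacity (128 kB
#' holding just over 100 s at 630 Hz), not a published fact.
#'
#' @param buffer_bytes buffer size in bytes (default 131072 = 128 kB).
#' @param bytes_per_sample stored word size (default 2).
#' @param fs_base base sampling rate, Hz (default 630).
#' @param decimation samples averaged per stored value; a power of two in
#'   1..1024.
#' @return An object of class `loop_recorder_config`.
#' @export
loop_recorder_config <- function(buffer_bytes = 131072, bytes_per_sample = 2,
                                 fs_base = 630, decimation = 1) {
  if (buffer_bytes <= 0) stop("'buffer_bytes' must be positive")
  if (!(decimation %in% 2^(0:10))) {
    stop("'decimation' must be a power of two in 1..1024")
  }
  structure(list(buffer_bytes = buffer_bytes,
                 bytes_per_sample = bytes_per_sample,
                 fs_base = fs_base, decimation = decimation),
            class = "loop_recorder_config")
}

#' Storage period of the loop recorder
#'
#' Seconds between stored values: `decimation / fs_base`. With the defaults
#' this spans 1.587 ms (raw signal) to 1.625 s (decimation 1024).
#'
#' @param cfg a [loop_recorder_config()].
#' @return storage period in seconds.
#' @export
storage_period_s <- function(cfg) {
  stopifnot(inherits(cfg, "loop_recorder_config"))
  cfg$decimation / cfg$fs_base
}

#' Loop-recorder capacity
#'
#' Number of stored samples the buffer holds and the time span they cover.
#' At the defaults (128 kB, 16-bit, 630 Hz, no decimation): 65,536 samples,
#' about 104 s of raw signal. Logging power-in-band at 0.5 Hz covers more
#' than 36 hours.
#'
#' @param cfg a [loop_recorder_config()].
#' @return list with `n_samples` and `seconds`.
#' @examples
#' recorder_capacity(loop_recorder_config())                    # ~104 s
#' recorder_capacity(loop_recorder_config(decimation = 1024))   # ~29.6 h
#' @export
recorder_capacity <- function(cfg) {
  stopifnot(inherits(cfg, "loop_recorder_config"))
  n <- floor(cfg$buffer_bytes / cfg$bytes_per_sample)
  list(n_samples = n, seconds = n * storage_period_s(cfg))
}

#' Initialise a loop-recorder buffer
#' @param cfg a [loop_recorder_config()].
#' @return a `loop_recorder` buffer state (empty).
#' @export
recorder_init <- function(cfg) {
  structure(list(cfg = cfg, values = numeric(0), total_written = 0),
            class = "loop_recorder")
}

#' Write decimated values into the circular recorder
#'
#' Ring-buffer semantics: the buffer retains exactly the most recent
#' `capacity` values, in order; older values are overwritten.
#'
#' @param buf a `loop_recorder` from [recorder_init()].
#' @param values decimated (block-mean) envelope values to append.
#' @return the updated `loop_recorder`.
#' @export
recorder_write <- function(buf, values) {
  stopifnot(inherits(buf, "loop_recorder"))
  n <- recorder_capacity(buf$cfg)$n_samples
  v <- c(buf$values, as.numeric(values))
  if (length(v) > n) v <- v[(length(v) - n + 1L):length(v)]
  buf$values <- v
  buf$total_written <- buf$total_written + length(values)
  buf
}

# mean over consecutive blocks of `dec` samples (tail partial block dropped)
decimate_mean <- function(v, dec) {
  if (dec == 1L) return(v)
  nb <- length(v) %/% dec
  if (nb == 0L) return(numeric(0))
  colMeans(matrix(v[seq_len(nb * dec)], nrow = dec))
}

# slot index (1..48) for clock seconds
slot_of <- function(clock_s) as.integer(floor((clock_s %% 86400) / 1800)) + 1L

#' Run a scheduled sensing/stimulation session
#'
#' Replays a biopotential trace through the device emulation under a 48-slot
#' schedule: at each slot boundary the active profile's chain, classifier
#' and policy take effect; the classifier runs on the stream named by the
#' profile (`envelope` or `motion`); LOW-to-HIGH threshold crossings are
#' counted per half-hour slot (the device logs counts, not timings); the
#' stimulation amplitude ramps across the whole session; and the decimated
#' envelope is written to the circular loop recorder.
#'
#' Filter and classifier state are reset when the active profile changes
#' (profiles may change bands, making state carry-over meaningless); the
#' stimulation amplitude is continuous across switches. With
#' `reset_at_boundaries = TRUE` state is reset at every slot boundary
#' instead.
#'
#' @param x a [raw_signal()]; `x$t0` and the duration define the covered
#'   slots.
#' @param schedule a [device_schedule()].
#' @param motion optional [motion_signal()] (required if any scheduled
#'   profile classifies the motion stream), assumed to start at `x$t0`.
#' @param recorder a [loop_recorder_config()], or `NULL` to skip recording.
#' @param time_scale wall-clock seconds represented by one signal second
#'   (1 = real time). A 24-h day can be emulated by a 864 s trace with
#'   `time_scale = 100`; debounce and time constants stay in signal seconds.
#' @param impedance_kohm electrode impedance for compliance checking.
#' @param reset_at_boundaries reset filter/classifier state at every slot
#'   boundary, not only at profile changes.
#' @param quantize quantise recorded envelope values to the chain's
#'   `quant_uv` step.
#' @return A `device_log`: per-sample `amplitude_ma` and `envelope`,
#'   `transitions` (with slot attribution), `crossings_per_slot` (48
#'   integers), the loop-recorder snapshot and compliance warnings.
#' @export
run_session <- function(x, schedule, motion = NULL, recorder = NULL,
                        time_scale = 1, impedance_kohm = 1.2,
                        reset_at_boundaries = FALSE, quantize = TRUE) {
  run_engine(x, schedule, artefact_model(0), motion = motion,
             recorder = recorder, time_scale = time_scale,
             impedance_kohm = impedance_kohm,
             reset_at_boundaries = reset_at_boundaries, quantize = quantize)
}

# Shared per-segment engine behind run_session (artefact gain 0) and
# run_closed_loop: the per-sample device emulation runs in C++, this wrapper
# handles scheduling, profile switching, slot-attributed bookkeeping and the
# loop recorder.
run_engine <- function(x, schedule, model, motion = NULL, recorder = NULL,
                       time_scale = 1, impedance_kohm = 1.2,
                       reset_at_boundaries = FALSE, quantize = TRUE) {
  stopifnot(inherits(x, "raw_signal"), inherits(schedule, "device_schedule"),
            inherits(model, "artefact_model"))
  n <- length(x$samples)
  t0s <- parse_clock(x$t0)
  clock <- t0s + (seq_len(n) - 1) / x$fs * time_scale
  slot_seq <- slot_of(clock)
  prof_seq <- schedule$slots[slot_seq]

  seg_key <- if (reset_at_boundaries) paste(prof_seq, slot_seq) else prof_seq
  seg_id <- cumsum(c(TRUE, seg_key[-1L] != seg_key[-n]))
  seg_starts <- which(!duplicated(seg_id))
  seg_ends <- c(seg_starts[-1L] - 1L, n)

  warnings <- character(0)
  for (id in unique(schedule$slots)) {
    p <- schedule$profiles[[id]]
    v <- validate_profile(p)
    hard <- v[!startsWith(v, "warning:")]
    if (length(hard)) stop("profile ", id, " invalid: ", hard[1L])
    warnings <- c(warnings, v[startsWith(v, "warning:")])
    imax <- max_deliverable_current(impedance_kohm)
    if (p$policy$active_ma > imax) {
      warnings <- c(warnings,
        sprintf("compliance: profile %s requests %.2f mA but only %.2f mA deliverable into %.2f kOhm",
                id, p$policy$active_ma, imax, impedance_kohm))
    }
  }

  env_all <- numeric(n); amp_all <- numeric(n)
  sensed_all <- numeric(n); art_all <- numeric(n)
  trans <- list()
  amp_prev <- NULL
  mclock <- NULL
  if (!is.null(motion)) {
    stopifnot(inherits(motion, "motion_signal"))
    mclock <- t0s + (seq_along(motion$values) - 1) / motion$fs * time_scale
  }

  for (k in seq_along(seg_starts)) {
    i0 <- seg_starts[k]; i1 <- seg_ends[k]
    p <- schedule$profiles[[prof_seq[i0]]]
    if (is.null(amp_prev)) amp_prev <- p$policy$baseline_ma

    forced <- NULL; tr_t <- numeric(0); tr_d <- integer(0)
    if (p$classifier$source == "motion") {
      if (is.null(motion)) {
        stop("profile ", p$id, " classifies the motion stream but no motion ",
             "signal was supplied")
      }
      sel <- which(mclock >= clock[i0] & mclock < clock[i1] + time_scale / x$fs)
      res_m <- classify_cpp(motion$values[sel], motion$fs,
                            p$classifier$threshold_uv, p$classifier$debounce_s)
      # map motion-grid states/transitions onto the signal grid
      tm <- (sel - 1) / motion$fs        # signal-time of the motion samples
      ts <- (i0:i1 - 1) / x$fs
      idx_m <- pmin(pmax(findInterval(ts, tm), 1L),
                    max(length(res_m$states), 1L))
      forced <- if (length(res_m$states)) res_m$states[idx_m]
                else integer(i1 - i0 + 1L)
      tr_t <- tm[res_m$idx + 1L]
      tr_d <- res_m$dir
    }

    sos <- butter_sos(p$chain$band_lo_hz, p$chain$band_hi_hz, x$fs)
    res <- closed_loop_cpp(
      x$samples[i0:i1], x$fs,
      dc_coef(p$chain$offset_cutoff_hz, x$fs), sos,
      ema_alpha(p$chain$ema_tau_s, x$fs),
      p$classifier$threshold_uv, p$classifier$debounce_s,
      p$policy$baseline_ma, p$policy$active_ma, p$policy$ramp_ma_per_pulse,
      p$policy$freq_hz, p$policy$baseline_freq_hz,
      model$gain_uv_per_ma, model$biphasic, p$policy$sham,
      amp_prev, forced)
    env_all[i0:i1] <- res$envelope
    amp_all[i0:i1] <- res$amplitude_ma
    sensed_all[i0:i1] <- res$sensed
    art_all[i0:i1] <- res$artefact
    amp_prev <- res$amplitude_ma[length(res$amplitude_ma)]
    if (is.null(forced)) {
      tr_t <- (i0 - 1 + res$idx) / x$fs
      tr_d <- res$dir
    }
    if (length(tr_t)) {
      trans[[length(trans) + 1L]] <- data.frame(
        time_s = tr_t, clock_s = t0s + tr_t * time_scale,
        direction = ifelse(tr_d > 0, "low_to_high", "high_to_low"),
        slot = slot_of(t0s + tr_t * time_scale),
        profile = p$id, stringsAsFactors = FALSE)
    }
  }

  transitions <- if (length(trans)) do.call(rbind, trans) else
    data.frame(time_s = numeric(0), clock_s = numeric(0),
               direction = character(0), slot = integer(0),
               profile = character(0), stringsAsFactors = FALSE)
  crossings_per_slot <- integer(48L)
  up <- transitions[transitions$direction == "low_to_high", , drop = FALSE]
  if (nrow(up)) {
    crossings_per_slot <- as.integer(table(factor(up$slot, levels = 1:48)))
  }

  rec <- NULL
  if (!is.null(recorder)) {
    stopifnot(inherits(recorder, "loop_recorder_config"))
    stored <- decimate_mean(env_all, recorder$decimation)
    if (quantize) {
      q <- schedule$profiles[[prof_seq[1L]]]$chain$quant_uv
      stored <- quantize_uv(stored, q)
    }
    rec <- recorder_write(recorder_init(recorder), stored)
  }

  structure(list(amplitude_ma = amp_all,
                 envelope = envelope_signal(pmax(env_all, 0), x$fs, x$t0),
                 sensed = raw_signal(sensed_all, x$fs, x$t0),
                 artefact = art_all,
                 fs = x$fs, t0 = x$t0, time_scale = time_scale,
                 transitions = transitions,
                 crossings_per_slot = crossings_per_slot,
                 recorder = rec, warnings = unique(warnings)),
            class = "device_log")
}

#' @export
print.device_log <- function(x, ...) {
  cat(sprintf("<device_log> %d samples @ %g Hz (time scale %gx), %d crossings\n",
              length(x$amplitude_ma), x$fs, x$time_scale,
              sum(x$crossings_per_slot)))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
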