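#' Simulation configuration
#'
#' Shared parameters for the seeded physiological signal generators. All
#' generators draw from sub-streams derived deterministically from `seed`
#' and the generator name, so an identical `sim_config` yields byte-identical
#' output regardless of generator call order.
#'
#' @param duration_s trace duration in (signal) seconds.
#' @param fs sampling rate, Hz (device base rate 630).
#' @param seed integer random seed.
#' @param background_rms_uv RMS of the 1/f background, microvolts.
#' @param background_beta spectral exponent of the `1/f^beta` background.
#' @param background_mod_depth depth of the slow (~30 s timescale) RMS
#'   modulation of the background, emulating the nonstationarity of resting
#'   LFP; 0 gives a stationary background.
#' @param t0 wall-clock start time.
#' @param time_scale wall-clock seconds per signal second (for
#'   time-compressed day-scale simulations; diurnal modulation follows the
#'   wall clock).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration_s, fs = 630, seed = 1,
                       background_rms_uv = 10, background_beta = 1,
                       background_mod_depth = 0.3,
                       t0 = "00:00:00", time_scale = 1) {
  if (duration_s <= 0) stop("'duration_s' must be positive")
  if (background_mod_depth < 0 || background_mod_depth >= 1) {
    stop("'background_mod_depth' must lie in [0, 1)")
  }
  structure(list(duration_s = duration_s, fs = fs, seed = as.integer(seed),
                 background_rms_uv = background_rms_uv,
                 background_beta = background_beta,
                 background_mod_depth = background_mod_depth,
                 t0 = t0, time_scale = time_scale),
            class = "sim_config")
}

# deterministic sub-seed per generator name (stays below 2^31)
sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629) + 1L
}

clock_at <- function(cfg, t) (parse_clock(cfg$t0) + t * cfg$time_scale) %% 86400

#' Diurnal modulation profile
#'
#' 48 half-hour multipliers in \[0, 1\] scaling event rate and amplitude
#' over the 24-h day. The default emulates the diurnal beta-power pattern
#' of a daytime plateau (06:00–22:00) and a low nighttime level, with a
#' one-slot intermediate transition at each boundary.
#'
#' @param day,night multiplier levels for the two phases.
#' @param day_start,day_end wall-clock phase boundaries (half-hour marks).
#' @param transition midpoint-valued transition slot at each boundary
#'   (the first and last slot of the day phase, so the night phase stays
#'   at its low level throughout).
#' @return numeric vector of length 48, class `diurnal_profile`.
#' @export
diurnal_profile <- function(day = 1, night = 0.2, day_start = "06:00",
                            day_end = "22:00", transition = TRUE) {
  if (any(c(day, night) < 0) || any(c(day, night) > 1)) {
    stop("multipliers must lie in [0, 1]")
  }
  s0 <- parse_clock(day_start) / 1800
  s1 <- parse_clock(day_end) / 1800
  idx <- 0:47
  in_day <- if (s0 <= s1) idx >= s0 & idx < s1 else idx >= s0 | idx < s1
  v <- ifelse(in_day, day, night)
  if (transition) {
    v[(s0 %% 48) + 1] <- (day + night) / 2          # first day slot
    v[((s1 - 1) %% 48) + 1] <- (day + night) / 2    # last day slot
  }
  structure(v, class = "diurnal_profile")
}

profile_mult <- function(profile, clock_s) {
  unclass(profile)[slot_of(clock_s)]
}

# band-limited Gaussian noise at a target RMS (uses the device band-pass)
bandlimited_noise <- function(n, fs, lo, hi, rms) {
  w <- sos_filter_cpp(rnorm(n), butter_sos(lo, hi, fs))
  r <- sqrt(mean(w^2))
  if (r > 0) w * (rms / r) else w
}

# raised-cosine on/off taper (taper_s each side), flat in between
taper_window <- function(n, fs, taper_s = 0.1) {
  nt <- min(floor(taper_s * fs), floor(n / 2))
  w <- rep(1, n)
  if (nt > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nt) / nt))
    w[seq_len(nt)] <- ramp
    w[(n - nt + 1):n] <- rev(ramp)
  }
  w
}

#' 1/f background activity
#'
#' Zero-mean Gaussian noise with a `1/f^beta` amplitude spectrum, scaled to
#' the configured RMS — the resting LFP floor on which all event generators
#' superimpose their activity. A slow multiplicative RMS modulation
#' (`background_mod_depth`, ~30 s timescale) reproduces the nonstationarity
#' of resting recordings, so that a broadband power step is not trivially
#' separable from baseline drift.
#'
#' @param cfg a [sim_config()].
#' @return a [raw_signal()].
#' @export
gen_background <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- round(cfg$duration_s * cfg$fs)
  if (cfg$background_rms_uv == 0) {
    return(raw_signal(numeric(n), cfg$fs, cfg$t0))
  }
  set.seed(sub_seed(cfg$seed, "background"))
  # synthesise on a 2-3-5-smooth length (fast mixed-radix FFT), then truncate
  n2 <- stats::nextn(n, c(2L, 3L, 5L))
  w <- rnorm(n2)
  k <- 0:(n2 - 1)
  f <- pmin(k, n2 - k) * cfg$fs / n2             # analogue frequency per bin
  shape <- ifelse(f > 0, f^(-cfg$background_beta / 2), 0)
  y <- Re(fft(fft(w) * shape, inverse = TRUE))[seq_len(n)] / n2
  y <- y - mean(y)
  y <- y * cfg$background_rms_uv / sqrt(mean(y^2))
  if (cfg$background_mod_depth > 0) {
    # slow log-normal-ish RMS drift: smoothed Gaussian walk, ~30 s timescale
    slow <- ema_cpp(rnorm(n), 1 - exp(-1 / (30 * cfg$fs)))
    slow <- slow / max(stats::sd(slow), 1e-12)
    mod <- 1 + cfg$background_mod_depth * pmax(pmin(slow, 2.5), -2.5) / 2.5
    y <- y * mod
    y <- y * cfg$background_rms_uv / sqrt(mean(y^2))
  }
  raw_signal(y, cfg$fs, cfg$t0)
}

# sequential non-overlapping Poisson onsets, thinned by a diurnal profile
poisson_events <- function(cfg, rate_hz, dur_fun, profile = NULL) {
  onsets <- numeric(0); offsets <- numeric(0); mults <- numeric(0)
  t <- 0
  if (rate_hz <= 0) {
    return(data.frame(onset_s = onsets, offset_s = offsets, mult = mults))
  }
  repeat {
    t <- t + rexp(1, rate_hz)
    if (t >= cfg$duration_s) break
    m <- if (is.null(profile)) 1 else profile_mult(profile, clock_at(cfg, t))
    if (m <= 0 || runif(1) > m) next
    d <- dur_fun()
    if (t + d > cfg$duration_s) next
    onsets <- c(onsets, t); offsets <- c(offsets, t + d); mults <- c(mults, m)
    t <- t + d
  }
  data.frame(onset_s = onsets, offset_s = offsets, mult = mults)
}

#' Diurnally modulated beta bursts
#'
#' Pseudo-random bursts of a 20 Hz oscillation (length 0.25–3 s, raised-
#' cosine tapers) on the 1/f background, with burst rate and amplitude
#' scaled by a diurnal profile — the Parkinsonian subthalamic LFP model.
#'
#' @param cfg a [sim_config()].
#' @param profile a [diurnal_profile()] scaling rate and amplitude.
#' @param rate_hz Poisson burst rate at multiplier 1, bursts/s.
#' @param amp_uv burst amplitude at multiplier 1, microvolts.
#' @param freq_hz burst oscillation frequency (beta peak 20 Hz).
#' @param dur_range_s burst duration range, seconds.
#' @return list with `signal` (a [raw_signal()]) and `annotations`
#'   (data frame `onset_s`, `offset_s`, `label`).
#' @export
gen_beta_bursts <- function(cfg, profile = diurnal_profile(), rate_hz = 0.15,
                            amp_uv = 30, freq_hz = 20,
                            dur_range_s = c(0.25, 3)) {
  stopifnot(inherits(cfg, "sim_config"))
  bg <- gen_background(cfg)
  set.seed(sub_seed(cfg$seed, "beta_bursts"))
  ev <- poisson_events(cfg, rate_hz,
                       function() runif(1, dur_range_s[1], dur_range_s[2]),
                       profile)
  y <- bg$samples
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      i0 <- round(ev$onset_s[i] * cfg$fs) + 1L
      i1 <- min(round(ev$offset_s[i] * cfg$fs), length(y))
      tt <- (i0:i1 - 1) / cfg$fs
      ph <- runif(1, 0, 2 * pi)
      burst <- amp_uv * ev$mult[i] * sin(2 * pi * freq_hz * tt + ph)
      y[i0:i1] <- y[i0:i1] + burst * taper_window(length(tt), cfg$fs)
    }
  }
  ann <- data.frame(onset_s = ev$onset_s, offset_s = ev$offset_s,
                    label = rep("burst", nrow(ev)), stringsAsFactors = FALSE)
  list(signal = raw_signal(y, cfg$fs, cfg$t0), annotations = ann)
}

#' Electrographic seizure events
#'
#' Seizures are modelled by their spectral signature as seen by a band-power
#' classifier: a broadband gain on the background plus a stronger band-
#' limited 10–20 Hz component. A `day_night` profile shifts the non-seizure
#' 10–20 Hz baseline floor across the day (the day/night baseline-power
#' shift that motivates diurnal classifier biasing). `layout =
#' "concatenated"` reproduces the bench preparation in which each event is
#' kept with 10 s of signal before and after and the slices are recombined;
#' the trace duration is then derived from the events.
#'
#' @param cfg a [sim_config()] (for `layout = "spread"` the events are
#'   placed within `cfg$duration_s`).
#' @param n_events number of seizure events.
#' @param day_night optional [diurnal_profile()] scaling the baseline
#'   in-band floor.
#' @param layout `"spread"` or `"concatenated"` (10 s pre/post slices).
#' @param pre_post_s padding per event in the concatenated layout.
#' @param dur_range_s event duration range, seconds (events are >= 3 s by
#'   the annotation rule).
#' @param band seizure-diagnostic band, Hz.
#' @param g_broad broadband gain applied to the background during events.
#' @param event_band_rms_uv RMS of the added in-band component during
#'   events (before the per-event intensity scale).
#' @param event_scale_range per-event intensity scale range (uniform), so
#'   weak events are reliably visible only in the diagnostic band.
#' @param floor_band_rms_uv RMS of the in-band baseline floor (scaled by
#'   `day_night`).
#' @return list with `signal` and `annotations` (`label = "seizure"`).
#' @export
gen_seizures <- function(cfg, n_events = 19, day_night = NULL,
                         layout = c("spread", "concatenated"),
                         pre_post_s = 10, dur_range_s = c(8, 30),
                         band = c(10, 20), g_broad = 1.3,
                         event_band_rms_uv = 12,
                         event_scale_range = c(0.7, 1.3),
                         floor_band_rms_uv = 3) {
  stopifnot(inherits(cfg, "sim_config"))
  layout <- match.arg(layout)
  if (dur_range_s[1] < 3) stop("annotated seizures must last at least 3 s")
  set.seed(sub_seed(cfg$seed, "seizures"))
  durs <- if (n_events > 0) runif(n_events, dur_range_s[1], dur_range_s[2])
          else numeric(0)

  if (layout == "concatenated") {
    total <- sum(durs) + 2 * pre_post_s * n_events
    cfg$duration_s <- max(total, 1)
    onsets <- pre_post_s + c(0, cumsum(head(durs, -1) + 2 * pre_post_s))
  } else {
    # even placement with jitter, non-overlapping with margins
    if (n_events > 0) {
      gap <- (cfg$duration_s - sum(durs)) / (n_events + 1)
      if (gap <= 1) stop("duration too short for the requested events")
      onsets <- numeric(n_events)
      t <- 0
      for (i in seq_len(n_events)) {
        t <- t + gap * runif(1, 0.5, 1.5)
        onsets[i] <- min(t, cfg$duration_s - durs[i] - 1)
        t <- onsets[i] + durs[i]
      }
    } else onsets <- numeric(0)
  }

  bg <- gen_background(cfg)
  set.seed(sub_seed(cfg$seed, "seizure_components"))
  n <- length(bg$samples)
  y <- bg$samples
  if (floor_band_rms_uv > 0) {
    floor_noise <- bandlimited_noise(n, cfg$fs, band[1], band[2],
                                     floor_band_rms_uv)
    if (!is.null(day_night)) {
      mult <- profile_mult(day_night, clock_at(cfg, (seq_len(n) - 1) / cfg$fs))
      floor_noise <- floor_noise * mult
    }
    y <- y + floor_noise
  }
  for (i in seq_along(onsets)) {
    i0 <- round(onsets[i] * cfg$fs) + 1L
    i1 <- min(round((onsets[i] + durs[i]) * cfg$fs), n)
    len <- i1 - i0 + 1L
    w <- taper_window(len, cfg$fs, 0.25)
    sc <- runif(1, event_scale_range[1], event_scale_range[2])
    y[i0:i1] <- y[i0:i1] + sc * (g_broad - 1) * bg$samples[i0:i1] * w +
      bandlimited_noise(len, cfg$fs, band[1], band[2],
                        sc * event_band_rms_uv) * w
  }
  ann <- data.frame(onset_s = onsets, offset_s = onsets + durs,
                    label = rep("seizure", length(onsets)),
                    stringsAsFactors = FALSE)
  list(signal = raw_signal(y, cfg$fs, cfg$t0), annotations = ann)
}

#' Nocturnal gamma-band epochs
#'
#' Repeating epochs of band-limited 55–65 Hz activity separated by quiet
#' gaps, emulating the sleep-associated thalamic gamma feature: epoch
#' durations follow a truncated normal with mean 8.1 min on \[2.9, 11.9\]
#' min. The default in-epoch amplitude is calibrated so the 80 uV envelope
#' threshold is crossed during epochs.
#'
#' @param cfg a [sim_config()].
#' @param mean_min,sd_min,range_min truncated-normal duration parameters,
#'   minutes.
#' @param gap_range_min quiet-gap range between epochs, minutes.
#' @param epoch_rms_uv in-epoch RMS of the 55–65 Hz component, microvolts
#'   (rectified-mean envelope is about 0.8 x RMS, so 140 uV clears the
#'   80 uV threshold).
#' @param band gamma band, Hz.
#' @return list with `signal` and `annotations` (`label = "gamma_epoch"`).
#' @export
gen_gamma_epochs <- function(cfg, mean_min = 8.1, sd_min = 2.25,
                             range_min = c(2.9, 11.9),
                             gap_range_min = c(4, 12), epoch_rms_uv = 140,
                             band = c(55, 65)) {
  stopifnot(inherits(cfg, "sim_config"))
  bg <- gen_background(cfg)
  set.seed(sub_seed(cfg$seed, "gamma_epochs"))
  pa <- pnorm(range_min[1], mean_min, sd_min)
  pb <- pnorm(range_min[2], mean_min, sd_min)
  onsets <- numeric(0); offsets <- numeric(0)
  t <- runif(1, 0, gap_range_min[2] * 60 / 2)
  repeat {
    d <- qnorm(runif(1, pa, pb), mean_min, sd_min) * 60
    if (t + d > cfg$duration_s) break
    onsets <- c(onsets, t); offsets <- c(offsets, t + d)
    t <- t + d + runif(1, gap_range_min[1], gap_range_min[2]) * 60
  }
  y <- bg$samples
  for (i in seq_along(onsets)) {
    i0 <- round(onsets[i] * cfg$fs) + 1L
    i1 <- min(round(offsets[i] * cfg$fs), length(y))
    len <- i1 - i0 + 1L
    y[i0:i1] <- y[i0:i1] +
      bandlimited_noise(len, cfg$fs, band[1], band[2], epoch_rms_uv) *
      taper_window(len, cfg$fs, 1)
  }
  ann <- data.frame(onset_s = onsets, offset_s = offsets,
                    label = rep("gamma_epoch", length(onsets)),
                    stringsAsFactors = FALSE)
  list(signal = raw_signal(y, cfg$fs, cfg$t0), annotations = ann)
}

#' Theta-alpha drowsiness events
#'
#' Transient 5–10 Hz rhythmic events (1–30 s) on the background — the
#' cortical signature of eye closure and microsleep onset used by the
#' daytime arousal-restoring classifier. Each event is an oscillation whose
#' instantaneous frequency wanders slowly within the band (drowsiness
#' theta-alpha is rhythmic, so the in-event envelope is stable and each
#' event yields a single threshold crossing under a debounced classifier).
#' Per-event intensity varies so that a threshold increase reduces, never
#' raises, the crossing count.
#'
#' @param cfg a [sim_config()].
#' @param n_events number of events to place.
#' @param dur_range_s event duration range, seconds.
#' @param env_target_range_uv range of per-event target power-in-band
#'   envelope levels, microvolts (tone amplitude is `target * pi / 2`).
#' @param gap_range_s quiet-gap range between events, seconds.
#' @param band theta-alpha band, Hz.
#' @return list with `signal` and `annotations` (`label = "theta_alpha"`).
#' @export
gen_theta_alpha_events <- function(cfg, n_events = 32,
                                   dur_range_s = c(1, 30),
                                   env_target_range_uv = c(40, 80),
                                   gap_range_s = c(10, 40),
                                   band = c(5, 10)) {
  stopifnot(inherits(cfg, "sim_config"))
  bg <- gen_background(cfg)
  set.seed(sub_seed(cfg$seed, "theta_alpha"))
  y <- bg$samples
  onsets <- numeric(0); offsets <- numeric(0)
  t <- runif(1, gap_range_s[1], gap_range_s[2])
  for (i in seq_len(n_events)) {
    d <- runif(1, dur_range_s[1], dur_range_s[2])
    if (t + d > cfg$duration_s) {
      warning(sprintf("duration fits only %d of %d events", i - 1L, n_events))
      break
    }
    target <- runif(1, env_target_range_uv[1], env_target_range_uv[2])
    i0 <- round(t * cfg$fs) + 1L
    i1 <- min(round((t + d) * cfg$fs), length(y))
    len <- i1 - i0 + 1L
    # slowly wandering instantaneous frequency within the band
    f_inst <- stats::filter(rnorm(len, 0, 0.02), 0.999, "recursive")
    f_inst <- mean(band) + (diff(band) / 2) * tanh(as.numeric(f_inst))
    phase <- 2 * pi * cumsum(f_inst) / cfg$fs + runif(1, 0, 2 * pi)
    y[i0:i1] <- y[i0:i1] +
      target * (pi / 2) * sin(phase) * taper_window(len, cfg$fs, 0.25)
    onsets <- c(onsets, t); offsets <- c(offsets, t + d)
    t <- t + d + runif(1, gap_range_s[1], gap_range_s[2])
  }
  ann <- data.frame(onset_s = onsets, offset_s = offsets,
                    label = rep("theta_alpha", length(onsets)),
                    stringsAsFactors = FALSE)
  list(signal = raw_signal(y, cfg$fs, cfg$t0), annotations = ann)
}

#' Triaxial motion traces
#'
#' 100 Hz accelerometer emulation: gravity baseline plus sensor noise, with
#' scheduled movement episodes (band-limited 0.5–4 Hz bursts on all axes)
#' and optional one-sample collision spikes shared by the three axes.
#' Values clip at the sensor's +-8 g range.
#'
#' @param cfg a [sim_config()] (`fs` is ignored; accelerometer rate is
#'   `fs_accel`).
#' @param episodes data frame with `onset_s`, `offset_s` of movement
#'   episodes (signal seconds).
#' @param fs_accel accelerometer rate, Hz.
#' @param episode_rms_g per-axis RMS of movement episodes, g.
#' @param noise_rms_g sensor noise RMS, g.
#' @param spike_times_s times of shared-axis collision spikes, seconds.
#' @param spike_g spike amplitude, g.
#' @return list with `ax`, `ay`, `az` (numeric, g), `fs`, `t0`, and
#'   `annotations` (`label = "movement"`).
#' @export
gen_motion <- function(cfg, episodes = NULL, fs_accel = 100,
                       episode_rms_g = 0.4, noise_rms_g = 0.01,
                       spike_times_s = NULL, spike_g = 6) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- round(cfg$duration_s * fs_accel)
  set.seed(sub_seed(cfg$seed, "motion"))
  acc <- list(ax = rnorm(n, 0, noise_rms_g),
              ay = rnorm(n, 0, noise_rms_g),
              az = 1 + rnorm(n, 0, noise_rms_g))
  if (!is.null(episodes) && nrow(episodes)) {
    for (i in seq_len(nrow(episodes))) {
      i0 <- round(episodes$onset_s[i] * fs_accel) + 1L
      i1 <- min(round(episodes$offset_s[i] * fs_accel), n)
      len <- i1 - i0 + 1L
      w <- taper_window(len, fs_accel, 0.5)
      for (axis in c("ax", "ay", "az")) {
        acc[[axis]][i0:i1] <- acc[[axis]][i0:i1] +
          bandlimited_noise(len, fs_accel, 0.5, 4, episode_rms_g) * w
      }
    }
  }
  for (ts in spike_times_s %||% numeric(0)) {
    k <- round(ts * fs_accel) + 1L
    if (k >= 1 && k <= n) for (axis in c("ax", "ay", "az")) {
      acc[[axis]][k] <- acc[[axis]][k] + spike_g
    }
  }
  for (axis in c("ax", "ay", "az")) {
    acc[[axis]] <- pmin(pmax(acc[[axis]], -8), 8)
  }
  ann <- if (!is.null(episodes) && nrow(episodes)) {
    data.frame(onset_s = episodes$onset_s, offset_s = episodes$offset_s,
               label = rep("movement", nrow(episodes)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(onset_s = numeric(0), offset_s = numeric(0),
               label = character(0), stringsAsFactors = FALSE)
  }
  c(acc, list(fs = fs_accel, t0 = cfg$t0, annotations = ann))
}
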