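test_that("generators are deterministic under the seed, regardless of order", {
  cfg <- sim_config(30, seed = 7)
  a <- gen_beta_bursts(cfg)
  b1 <- gen_background(cfg)
  a2 <- gen_beta_bursts(cfg)
  b2 <- gen_background(cfg)
  expect_identical(a$signal$samples, a2$signal$samples)
  expect_identical(a$annotations, a2$annotations)
  expect_identical(b1$samples, b2$samples)
  # different seeds diverge
  expect_false(identical(
    gen_background(sim_config(30, seed = 8))$samples, b1$samples))
})

test_that("background has the configured RMS and 1/f spectral slope", {
  cfg <- sim_config(200, seed = 30, background_rms_uv = 10,
                    background_mod_depth = 0)
  bg <- gen_background(cfg)
  expect_equal(sqrt(mean(bg$samples^2)), 10, tolerance = 1e-9)
  expect_equal(mean(bg$samples), 0, tolerance = 1e-9)

  sp <- stats::spec.pgram(stats::ts(bg$samples, frequency = 630),
                          spans = 15, plot = FALSE, taper = 0.1)
  sel <- sp$freq > 1 & sp$freq < 100
  fit <- stats::lm(log(sp$spec[sel]) ~ log(sp$freq[sel]))
  expect_lt(abs(unname(stats::coef(fit)[2]) - (-1)), 0.15)

  zero <- gen_background(sim_config(10, seed = 1, background_rms_uv = 0))
  expect_equal(zero$samples, numeric(6300))
})

test_that("beta bursts respect duration bounds and the diurnal profile", {
  ts <- 100
  cfg <- sim_config(86400 / ts, seed = 31, t0 = "06:00:00", time_scale = ts)
  gen <- gen_beta_bursts(cfg)
  durs <- gen$annotations$offset_s - gen$annotations$onset_s
  expect_gt(length(durs), 10)
  expect_true(all(durs >= 0.25 - 1e-9 & durs <= 3 + 1e-9))
  expect_true(all(diff(gen$annotations$onset_s) > 0))

  # higher daytime beta band power than nighttime (independent band-power
  # oracle on the day vs night portions of the trace)
  clock <- parse_clock("06:00:00") + (seq_along(gen$signal$samples) - 1) /
    630 * ts
  is_day <- (clock %% 86400) >= 6 * 3600 & (clock %% 86400) < 22 * 3600
  p_day <- band_power_oracle(gen$signal$samples[is_day], 630, 13, 30)
  p_night <- band_power_oracle(gen$signal$samples[!is_day], 630, 13, 30)
  expect_gt(p_day, 2 * p_night)

  # all-zero profile leaves pure background
  flat <- gen_beta_bursts(cfg, profile = diurnal_profile(day = 0, night = 0,
                                                         transition = FALSE))
  expect_equal(nrow(flat$annotations), 0L)
  expect_identical(flat$signal$samples, gen_background(cfg)$samples)
})

test_that("diurnal profile is a 48-vector in [0,1] with a low night phase", {
  p <- diurnal_profile()
  expect_length(unclass(p), 48L)
  expect_true(all(p >= 0 & p <= 1))
  # night slots (22:00-06:00) all at the low level
  night_idx <- c(1:12, 45:48)
  expect_true(all(unclass(p)[night_idx] == 0.2))
  expect_error(diurnal_profile(day = 1.5), "\\[0, 1\\]")
})

test_that("seizure generator produces the requested concatenated layout", {
  cfg <- sim_config(3600, seed = 32)
  gen <- gen_seizures(cfg, n_events = 19, layout = "concatenated",
                      pre_post_s = 10)
  expect_equal(nrow(gen$annotations), 19L)
  expect_equal(gen$annotations$onset_s[1], 10)
  # 10 s of padding separates consecutive events
  gaps <- gen$annotations$onset_s[-1] - gen$annotations$offset_s[-19]
  expect_true(all(abs(gaps - 20) < 1e-9))
  durs <- gen$annotations$offset_s - gen$annotations$onset_s
  expect_true(all(durs >= 3))

  # in-band (10-20 Hz) power during events exceeds baseline by >= 6 dB
  fs <- 630
  lab <- labels_from_annotations(gen$annotations, fs,
                                 length(gen$signal$samples))
  p_ev <- band_power_oracle(gen$signal$samples[lab == 1], fs, 10, 20)
  p_base <- band_power_oracle(gen$signal$samples[lab == 0], fs, 10, 20)
  expect_gt(10 * log10(p_ev / p_base), 6)

  none <- gen_seizures(cfg, n_events = 0)
  expect_equal(nrow(none$annotations), 0L)
})

test_that("gamma epochs follow the printed duration statistics", {
  cfg <- sim_config(2 * 3600, seed = 33)
  gen <- gen_gamma_epochs(cfg)
  durs_min <- (gen$annotations$offset_s - gen$annotations$onset_s) / 60
  expect_gte(length(durs_min), 5)
  expect_true(all(durs_min >= 2.9 & durs_min <= 11.9))
  expect_lt(abs(mean(durs_min) - 8.1) / 8.1, 0.15)

  # in-epoch envelope clears the 80 uV device threshold
  env <- power_in_band(gen$signal, chain_config(55, 65, ema_tau_s = 0.5))
  st <- threshold_classify(env, classifier_config(80, debounce_s = 10))
  expect_gte(st$crossings, length(durs_min) - 1)

  # without epochs the 80 uV classifier stays silent
  quiet <- gen_background(cfg)
  env0 <- power_in_band(quiet, chain_config(55, 65, ema_tau_s = 0.5))
  st0 <- threshold_classify(env0, classifier_config(80, debounce_s = 10))
  expect_equal(st0$crossings, 0L)
})

test_that("theta-alpha events drive the classifier monotonically in threshold", {
  cfg <- sim_config(1500, seed = 34)
  gen <- gen_theta_alpha_events(cfg, n_events = 32)
  expect_equal(nrow(gen$annotations), 32L)
  env <- power_in_band(gen$signal, chain_config(5, 10, ema_tau_s = 0.5))
  st38 <- threshold_classify(env, classifier_config(38, debounce_s = 10))
  st57 <- threshold_classify(env, classifier_config(57, debounce_s = 10))
  expect_lte(st38$crossings, 32L)
  expect_gt(st38$crossings, 0L)
  expect_lte(st57$crossings, st38$crossings)
})

test_that("annotated events carry their band's power (all generators)", {
  cases <- list(
    list(gen = function(cfg) gen_beta_bursts(cfg,
           profile = diurnal_profile(1, 1, transition = FALSE)),
         band = c(13, 30), dur = 400),
    list(gen = function(cfg) gen_seizures(cfg, n_events = 5), band = c(10, 20),
         dur = 400),
    list(gen = function(cfg) gen_theta_alpha_events(cfg, n_events = 6),
         band = c(5, 10), dur = 400))
  for (cs in cases) {
    cfg <- sim_config(cs$dur, seed = 35)
    g <- cs$gen(cfg)
    lab <- labels_from_annotations(g$annotations, 630,
                                   length(g$signal$samples))
    p_in <- band_power_oracle(g$signal$samples[lab == 1], 630,
                              cs$band[1], cs$band[2])
    p_out <- band_power_oracle(g$signal$samples[lab == 0], 630,
                               cs$band[1], cs$band[2])
    expect_gt(p_in, p_out)
  }
})

test_that("doubling the burst rate doubles event counts within Poisson error", {
  flat <- diurnal_profile(1, 1, transition = FALSE)
  n1 <- nrow(gen_beta_bursts(sim_config(1200, seed = 36), flat,
                             rate_hz = 0.1)$annotations)
  n2 <- nrow(gen_beta_bursts(sim_config(1200, seed = 37), flat,
                             rate_hz = 0.2)$annotations)
  # 3 sigma of the Poisson expectation (occupancy shortens exposure slightly)
  expect_lt(abs(n2 - 2 * n1), 3 * sqrt(2 * 120) + 0.15 * 2 * n1)
})

test_that("motion traces stay within the sensor range and trigger correctly", {
  cfg <- sim_config(600, seed = 38)
  quiet <- gen_motion(cfg)
  mm <- motion_magnitude(quiet$ax, quiet$ay, quiet$az, quiet$fs)
  expect_lt(stats::sd(mm$values), 0.05)   # near-constant without episodes

  episodes <- data.frame(onset_s = c(100, 400), offset_s = c(110, 410))
  mot <- gen_motion(cfg, episodes)
  mm2 <- motion_magnitude(mot$ax, mot$ay, mot$az, mot$fs)
  st <- motion_trigger(mm2, classifier_config(0.5, debounce_s = 20,
                                              source = "motion"))
  expect_equal(st$crossings, 2L)

  # spikes clip at the +-8 g sensor range
  spiky <- gen_motion(cfg, episodes, spike_times_s = 250, spike_g = 20)
  expect_true(all(abs(c(spiky$ax, spiky$ay, spiky$az)) <= 8))
  expect_equal(max(spiky$az), 8)
})
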