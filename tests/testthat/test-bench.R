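fs <- 630

test_that("artefact impulses land on the exact sample grid of the pulse train", {
  # 4 s of sustained HIGH at 126 Hz: pulses every 5th sample at fs 630
  st <- threshold_classify(envelope_signal(rep(100, 4 * fs), fs),
                           classifier_config(80, 0))
  amp <- ramp_stimulation(st, stim_policy(1, 1, freq_hz = 126),
                          keep_pulses = TRUE)
  art <- stim_artefact(amp, artefact_model(2, biphasic = FALSE), fs)
  nz <- which(art$samples != 0)
  expect_true(all((nz - 1) %% 5 == 0))
  expect_equal(art$samples[nz], rep(2, length(nz)))   # gain x 1 mA

  # 6 Hz baseline: every 105th sample
  amp6 <- ramp_stimulation(st, stim_policy(1, 1, freq_hz = 6),
                           keep_pulses = TRUE)
  art6 <- stim_artefact(amp6, artefact_model(2, biphasic = FALSE), fs)
  expect_true(all((which(art6$samples != 0) - 1) %% 105 == 0))

  # zero current -> zero artefact; biphasic pairs sum to zero charge
  amp0 <- ramp_stimulation(st, stim_policy(0, 0))
  amp0$pulse_times_s <- amp$pulse_times_s
  amp0$pulse_amps_ma <- rep(0, length(amp$pulse_amps_ma))
  expect_equal(stim_artefact(amp0, artefact_model(2), fs)$samples,
               rep(0, 4 * fs))
  # biphasic pairs are charge-balanced (up to a recovery impulse that can
  # fall just past the end of the trace)
  art_b <- stim_artefact(amp, artefact_model(2, biphasic = TRUE), fs)
  expect_lte(abs(sum(art_b$samples)), 2)
  nzb <- which(art_b$samples > 0)
  nzb <- nzb[nzb < length(art_b$samples)]
  expect_true(all(art_b$samples[nzb + 1L] < 0))
})

test_that("zero artefact gain decouples the loop and reproduces run_session", {
  cfg <- sim_config(120, seed = 41)
  gen <- gen_seizures(cfg, n_events = 3, layout = "spread")
  p <- suppressWarnings(stim_profile(
    "A", chain_config(10, 20, ema_tau_s = 1), classifier_config(8, 5),
    stim_policy(1, 4, baseline_freq_hz = 6)))
  sched <- device_schedule(rep("A", 48), list(A = p))
  open_loop <- run_session(gen$signal, sched)
  closed <- run_closed_loop(gen$signal, sched, artefact_model(0))
  expect_equal(closed$envelope$values, open_loop$envelope$values,
               tolerance = 1e-12)
  expect_equal(closed$amplitude_ma, open_loop$amplitude_ma,
               tolerance = 1e-12)
  expect_equal(closed$crossings_per_slot, open_loop$crossings_per_slot)
  expect_equal(closed$sensed$samples, gen$signal$samples)
})

test_that("the bench is additive and strictly causal", {
  cfg <- sim_config(60, seed = 42)
  gen <- gen_seizures(cfg, n_events = 2, layout = "spread",
                      dur_range_s = c(5, 10))
  p <- suppressWarnings(stim_profile(
    "A", chain_config(10, 20, ema_tau_s = 0.5), classifier_config(8, 2),
    stim_policy(1, 4, baseline_freq_hz = 6)))
  sched <- device_schedule(rep("A", 48), list(A = p))
  full <- run_closed_loop(gen$signal, sched, artefact_model(5))
  # superposition: sensed - artefact reconstructs the neural input exactly
  expect_equal(full$sensed$samples - full$artefact, gen$signal$samples)
  # prefix equivalence: no output sample depends on future inputs
  for (n in c(1000, 20000)) {
    pre <- run_closed_loop(raw_signal(gen$signal$samples[1:n], fs,
                                      gen$signal$t0),
                           sched, artefact_model(5))
    expect_equal(pre$sensed$samples, full$sensed$samples[1:n])
    expect_equal(pre$amplitude_ma, full$amplitude_ma[1:n])
  }
})

test_that("seizure detections switch the stimulation to 126 Hz artefact", {
  scn <- bench_scenario("epilepsy_adaptive", seed = 43)
  run <- run_scenario(scn)
  log <- run$log
  expect_gt(sum(log$crossings_per_slot), 0)
  # while HIGH at full amplitude, artefact pulses recur every 5 samples
  st <- log$transitions
  highs <- st$time_s[st$direction == "low_to_high"]
  ends <- st$time_s[st$direction == "high_to_low"]
  expect_gt(length(highs), 0)
  h1 <- highs[1]; e1 <- ends[ends > h1][1]
  mid <- round((h1 + 2) * fs):round(min(e1, h1 + 4) * fs)
  nz <- which(log$artefact[mid] != 0)
  expect_true(all(diff(nz) %in% c(1L, 4L, 5L)))   # biphasic pairs at period 5
  expect_gt(max(log$amplitude_ma), 1)             # adaptive switch engaged
  # every annotated seizure overlapping a HIGH state carries artefact energy
  lab <- labels_from_annotations(run$annotations, fs,
                                 length(log$artefact))
  high_mask <- rep(0L, length(lab))
  for (i in seq_along(highs)) {
    e <- ends[ends > highs[i]][1]
    if (is.na(e)) e <- length(lab) / fs
    high_mask[round(highs[i] * fs + 1):min(round(e * fs), length(lab))] <- 1L
  }
  both <- lab == 1L & high_mask == 1L
  expect_gt(sum(both), 0)
  expect_gt(sum(log$artefact[both] != 0), 0)
})

test_that("dual-profile day uses the beta classifier, night only motion", {
  scn <- bench_scenario("pd_dual_profile", seed = 44)
  run <- run_scenario(scn)
  tr <- run$log$transitions
  ups <- tr[tr$direction == "low_to_high", ]
  day_slots <- 13:44
  expect_gt(sum(ups$profile == "A"), 10)
  expect_true(all(ups$slot[ups$profile == "A"] %in% day_slots))
  expect_equal(sum(ups$profile == "B"), 2L)
  expect_true(all(!(ups$slot[ups$profile == "B"] %in% day_slots)))
})

test_that("classifier degradation is mild at default gain, strict when extreme", {
  scn0 <- bench_scenario("epilepsy_adaptive", seed = 45,
                         artefact = artefact_model(0))
  rep0 <- degradation_report(scn0)
  expect_identical(rep0$auc_on, rep0$auc_off)
  expect_identical(rep0$f1_on, rep0$f1_off)

  scn1 <- bench_scenario("epilepsy_adaptive", seed = 45)
  rep1 <- degradation_report(scn1)
  expect_lte(rep1$auc_off - rep1$auc_on, 0.10)
  expect_gt(rep1$auc_off, 0.9)

  scn10 <- bench_scenario("epilepsy_adaptive", seed = 45,
                          artefact = artefact_model(25))
  rep10 <- degradation_report(scn10)
  expect_lt(rep10$auc_on, rep10$auc_off)
})

test_that("126 Hz artefact perturbs the 10-20 Hz envelope only mildly", {
  scn <- bench_scenario("epilepsy_adaptive", seed = 46)
  p <- scn$schedule$profiles[["A"]]
  env_off <- power_in_band(scn$signal, p$chain)
  run <- run_scenario(scn)
  env_on <- run$log$envelope$values
  # exclude settling and +-2 s around stimulation state switches
  keep <- rep(TRUE, length(env_on))
  keep[seq_len(round(5 * p$chain$ema_tau_s * fs))] <- FALSE
  for (t in run$log$transitions$time_s) {
    keep[max(1, round((t - 2) * fs)):min(length(keep), round((t + 2) * fs))] <- FALSE
  }
  rel <- sqrt(mean((env_on[keep] - env_off$values[keep])^2)) /
    sqrt(mean(env_off$values[keep]^2))
  expect_lt(rel, 0.15)
})
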