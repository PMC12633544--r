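mk_profile <- function(id, source = "envelope", threshold = 80, sham = FALSE,
                       debounce = 0) {
  stim_profile(id, chain_config(13, 30, ema_tau_s = 0.25),
               suppressWarnings(classifier_config(threshold, debounce,
                                                  source = source)),
               stim_policy(0.5, 3, sham = sham))
}

test_that("the scheduler resolves half-open 30-min slots", {
  day <- mk_profile("A"); night <- mk_profile("B")
  sched <- schedule_day_night(day, night, "06:00", "22:00")
  expect_equal(active_profile("21:59:59", sched), "A")
  expect_equal(active_profile("22:00:00", sched), "B")
  expect_equal(active_profile("05:59:59", sched), "B")
  expect_equal(active_profile("06:00:00", sched), "A")
  all_a <- device_schedule(rep("A", 48), list(A = day))
  expect_equal(active_profile("13:13:13", all_a), "A")
  expect_error(active_profile("25:99", sched), "malformed")
})

test_that("schedules enforce device parity and defined profiles", {
  a <- mk_profile("A"); b <- mk_profile("B"); c3 <- mk_profile("C")
  expect_error(device_schedule(rep(c("A", "B", "C"), 16),
                               list(A = a, B = b, C = c3)),
               "at most 2")
  expect_message(device_schedule(rep(c("A", "B", "C"), 16),
                                 list(A = a, B = b, C = c3), research = TRUE),
                 "research")
  err <- tryCatch(device_schedule(c(rep("A", 40), rep("C", 8)), list(A = a)),
                  error = conditionMessage)
  expect_match(err, "slot 41")
  expect_match(err, "'C'")
})

test_that("profile validation flags contact sharing and soft bounds", {
  good <- stim_profile("A", chain_config(13, 30), classifier_config(12, 10),
                       stim_policy(0.5, 3, freq_hz = 126, pw_us = 90),
                       sense_contacts = c(1, 2), stim_contacts = c(3, 4))
  expect_length(validate_profile(good), 0)

  shared <- stim_profile("A", chain_config(13, 30), classifier_config(12, 10),
                         stim_policy(0.5, 3),
                         sense_contacts = c(1, 3), stim_contacts = c(3, 4))
  expect_match(validate_profile(shared), "sensing and stimulation")

  hot <- stim_profile("A", chain_config(13, 30), classifier_config(12, 10),
                      suppressWarnings(stim_policy(0.5, 5.0)))
  expect_match(validate_profile(hot), "warning: active_ma 5")
})

test_that("loop-recorder arithmetic matches the device figures", {
  cfg <- loop_recorder_config()
  expect_equal(round(storage_period_s(cfg) * 1000, 3), 1.587)
  expect_equal(round(storage_period_s(loop_recorder_config(decimation = 1024)), 3),
               1.625)
  expect_equal(storage_period_s(loop_recorder_config(decimation = 2)),
               2 * storage_period_s(cfg))

  cap <- recorder_capacity(cfg)
  expect_equal(cap$n_samples, 65536L)
  expect_gte(cap$seconds, 100)
  expect_equal(cap$seconds, 65536 / 630)
  expect_equal(recorder_capacity(loop_recorder_config(decimation = 1024))$seconds / 3600,
               29.6, tolerance = 0.01)
  # power-in-band logged at 0.5 Hz covers more than 30 hours
  cfg2 <- loop_recorder_config(fs_base = 0.5, decimation = 1)
  expect_gt(recorder_capacity(cfg2)$seconds / 3600, 30)

  # capacity is monotone in decimation and buffer size
  secs <- vapply(2^(0:10), function(d)
    recorder_capacity(loop_recorder_config(decimation = d))$seconds, 0)
  expect_true(all(diff(secs) > 0))
  expect_gt(recorder_capacity(loop_recorder_config(buffer_bytes = 2^18))$seconds,
            cap$seconds)
  expect_error(loop_recorder_config(decimation = 3), "power of two")
})

test_that("the circular recorder retains the newest values in order", {
  cfg <- loop_recorder_config(buffer_bytes = 20, bytes_per_sample = 2)
  buf <- recorder_init(cfg)   # capacity 10
  buf <- recorder_write(buf, 1:7)
  expect_equal(buf$values, as.numeric(1:7))
  buf <- recorder_write(buf, 8:15)
  expect_equal(buf$values, as.numeric(6:15))
  expect_equal(buf$total_written, 15)
  # a monotone ramp written past wrap-around reads back monotone
  buf2 <- recorder_write(recorder_init(cfg), seq(0, 5, by = 0.2))
  expect_true(all(diff(buf2$values) > 0))
  expect_length(buf2$values, 10)
})

test_that("a quiet day produces 48 empty slots and a recorder snapshot", {
  x <- raw_signal(numeric(864 * 63), fs = 63, t0 = "00:00:00")
  sched <- schedule_day_night(mk_profile("A"), mk_profile("B"))
  log <- run_session(x, sched, time_scale = 100,
                     recorder = loop_recorder_config(fs_base = 63,
                                                     decimation = 64))
  expect_length(log$crossings_per_slot, 48L)
  expect_equal(sum(log$crossings_per_slot), 0L)
  expect_equal(log$amplitude_ma, rep(0.5, length(x$samples)))
  expect_true(all(log$recorder$values == 0))
})

test_that("slot attribution matches a brute-force binning oracle", {
  # alternating ON/SHAM every 30 min over a compressed 6-h session
  fs <- 630
  ts <- 100
  cfg <- sim_config(6 * 3600 / ts, fs = fs, seed = 21, t0 = "09:00:00",
                    time_scale = ts)
  gen <- gen_theta_alpha_events(cfg, n_events = 12, dur_range_s = c(2, 6),
                                gap_range_s = c(5, 15), band = c(13, 30),
                                env_target_range_uv = c(40, 80))
  on <- mk_profile("A", threshold = 20)
  sham <- mk_profile("B", threshold = 20, sham = TRUE)
  sched <- device_schedule(rep(c("A", "B"), 24), list(A = on, B = sham))
  log <- run_session(gen$signal, sched, time_scale = ts)

  up <- log$transitions[log$transitions$direction == "low_to_high", ]
  expect_gt(nrow(up), 0)
  oracle_counts <- table(factor(slot_oracle(parse_clock("09:00:00") +
                                              up$time_s * ts),
                                levels = 1:48))
  expect_equal(log$crossings_per_slot, as.integer(oracle_counts))
  expect_equal(sum(log$crossings_per_slot), sum(up$direction == "low_to_high"))
  # parity: slots 09:00-09:30 etc alternate A (odd index 19) and B
  expect_true(all(up$profile == ifelse(up$slot %% 2 == 1, "A", "B")))
})

test_that("an identical-profile schedule splices into one continuous run", {
  fs <- 630
  cfg <- sim_config(120, fs = fs, seed = 22, t0 = "11:45:00", time_scale = 100)
  gen <- gen_beta_bursts(cfg, profile = diurnal_profile(day = 1, night = 1),
                         rate_hz = 0.3)
  p <- mk_profile("A", threshold = 12)
  both <- schedule_day_night(p, mk_profile("A", threshold = 12))
  one <- device_schedule(rep("A", 48), list(A = p))
  log_sched <- run_session(gen$signal, both, time_scale = 100)
  log_plain <- run_session(gen$signal, one, time_scale = 100)
  expect_equal(log_sched$envelope$values, log_plain$envelope$values)
  expect_equal(log_sched$amplitude_ma, log_plain$amplitude_ma)
  expect_equal(log_sched$crossings_per_slot, log_plain$crossings_per_slot)
})

test_that("motion-classifying profiles require a motion stream", {
  x <- raw_signal(numeric(6300), fs = 630, t0 = "23:00:00")
  night <- mk_profile("B", source = "motion", threshold = 0.5)
  sched <- device_schedule(rep("B", 48), list(B = night))
  expect_error(run_session(x, sched), "motion")
})
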