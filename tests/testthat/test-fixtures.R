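test_that("identity corruption leaves logged onsets equal to ground truth", {
  fx <- clean_fixture(n = 10, with_responses = FALSE)
  stim <- fx$log[fx$log$event_class == "controlled", ]
  expect_equal(stim$onset_s, fx$truth$onset_s)
  expect_equal(stim$planned_onset_s, fx$truth$onset_s)
  expect_true(all(diff(fx$truth$onset_s) > 0))
})

test_that("constant clock delay shifts every logged onset by exactly the delay", {
  fx <- generate_experiment(std_plan(20, with_responses = FALSE),
                            corruption_spec(clock_delay = 0.032), seed = 3)
  stim <- fx$log[fx$log$event_class == "controlled", ]
  expect_equal(fx$truth$onset_s - stim$onset_s, rep(0.032, 20))
})

test_that("injected Gaussian jitter is recovered from truth minus logged", {
  fx <- generate_experiment(
    experiment_plan(500, planned_durations = 0.2,
                    inter_event_interval = 0.3),
    corruption_spec(jitter_sd = 0.005), seed = 11
  )
  stim <- fx$log[fx$log$event_class == "controlled", ]
  resid <- fx$truth$onset_s - stim$onset_s
  # oracle: the drawn noise vector itself
  expect_equal(resid, -fx$injected$jitter_s)
  expect_lt(abs(sd(resid) - 0.005) / 0.005, 0.15)
})

test_that("label errors hit exactly the requested number of rows", {
  fx <- generate_experiment(std_plan(24, with_responses = FALSE),
                            corruption_spec(label_errors = 3), seed = 5)
  inj <- fx$injected$label_error_rows
  expect_equal(nrow(inj), 3)
  expect_true(all(inj$original != inj$corrupted))
  for (k in 1:3) {
    expect_identical(
      fx$log[[inj$field[k]]][fx$log$event_index == inj$event_index[k]],
      inj$corrupted[k]
    )
  }
})

test_that("dropped events shrink the log while truth is conserved", {
  fx <- generate_experiment(std_plan(30, with_responses = FALSE),
                            corruption_spec(drop_events = 4), seed = 9)
  expect_equal(nrow(fx$log), 30 - 4)
  expect_equal(nrow(fx$truth), 30)
  expect_equal(length(fx$injected$dropped_rows), 4)
})

test_that("generation is byte-identical under a fixed seed", {
  a <- generate_experiment(std_plan(15), corruption_spec(jitter_sd = 0.004),
                           seed = 42)
  b <- generate_experiment(std_plan(15), corruption_spec(jitter_sd = 0.004),
                           seed = 42)
  expect_identical(a$log, b$log)
  expect_identical(a$truth, b$truth)
})

test_that("non-monotonic corruption errors and names the first bad event", {
  plan <- experiment_plan(5, planned_durations = 0.01,
                          inter_event_interval = 0.01)
  expect_error(
    generate_experiment(plan, corruption_spec(jitter_sd = 0.5), seed = 2),
    "non-monotonic at event"
  )
})

test_that("photodiode synthesis places rectangular pulses at the truth times", {
  tr <- synthesize_photodiode(pulse_seq(0.1), fs = 1000, pulse_width = 0.02,
                              scheme = "onset_only")
  # 0-based samples 100..119 high, everything else at baseline
  expect_equal(which(tr$value == 1), 101:120)
  expect_true(all(tr$value[-(101:120)] == 0))

  empty <- synthesize_photodiode(pulse_seq(numeric(0)), fs = 1000,
                                 pulse_width = 0.02, scheme = "onset_only")
  expect_true(all(empty$value == 0))
  expect_gt(nrow(empty), 0)
})

test_that("overlapping flashes are rejected with the colliding indices", {
  expect_error(
    synthesize_photodiode(pulse_seq(c(0.1, 0.105)), fs = 1000,
                          pulse_width = 0.02, scheme = "onset_only"),
    "overlapping pulses.*1"
  )
})

test_that("keypress audio concentrates burst energy at the press times", {
  tr <- synthesize_keypress_audio(1.0, fs = 8000, click_duration = 0.01,
                                  snr = 10, seed = 1)
  in_burst <- tr$time_s >= 1.0 & tr$time_s < 1.01
  expect_gt(mean(tr$value[in_burst]^2), 20 * mean(tr$value[!in_burst]^2))

  silent <- synthesize_keypress_audio(numeric(0), fs = 8000, seed = 1)
  expect_lt(max(abs(silent$value)), 0.05)
})

test_that("trigger synthesis preserves codes and applies the clock model", {
  tt <- c(1, 2, 3)
  trig0 <- synthesize_triggers(tt, codes = c("a", "b", "a"))
  expect_equal(trig0$timestamp_s, tt)
  expect_equal(trig0$code, c("a", "b", "a"))

  trig <- synthesize_triggers(tt, codes = 1:3, delay = 0.030)
  # Eq.8-style estimator (physical - trigger) recovers +delay exactly
  expect_equal(trigger_delay(tt, trig)$delta_s, rep(0.030, 3))
})

test_that("trigger jitter SD propagates into the interval metric as sqrt(2)*sd", {
  n <- 1000
  tt <- cumsum(rep(0.8, n))
  trig <- synthesize_triggers(tt, codes = rep(1, n), jitter_sd = 0.002,
                              seed = 21)
  ds <- trigger_jitter(tt, trig)
  expect_lt(abs(glance(ds)$sd_s - 0.002 * sqrt(2)) / (0.002 * sqrt(2)),
            0.15)
  expect_lt(abs(glance(ds)$mean_s), 5e-4)
})

test_that("plan and corruption YAML round-trips reconstruct the objects", {
  f1 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(list(
    n_events = 8,
    factors = list(category = c("face", "object")),
    planned_durations = 0.4,
    inter_event_interval = 0.8,
    response_plan = list(key = c("f", "j"), presses = c(1, 2))
  )), f1)
  plan <- read_plan(f1)
  expect_s3_class(plan, "experiment_plan")
  expect_equal(plan$n_events, 8L)
  expect_equal(plan$response_plan$presses, c(1L, 2L))

  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(list(clock_delay = 0.01, label_errors = 2)), f2)
  corr <- read_corruption(f2)
  expect_equal(corr$clock_delay, 0.01)
  expect_equal(corr$label_errors, 2L)
})
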