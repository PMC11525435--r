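test_that("interval series is the discrete difference of the timestamps", {
  expect_equal(interval_series(c(0, 1, 2.5)), c(1, 1.5))
  expect_equal(interval_series(seq(2, 10, by = 0.7)),
               rep(0.7, 11), tolerance = 1e-12)
  # brute-force pairwise-subtraction oracle on a random increasing vector
  x <- withr::with_seed(3, sort(runif(50, 0, 100)))
  oracle <- vapply(seq_len(49), function(i) x[i + 1] - x[i], 0)
  expect_equal(interval_series(x), oracle)
  expect_error(interval_series(1.5), "at least 2")
})

test_that("logging inaccuracy follows the physical-minus-log interval convention", {
  ds <- logging_inaccuracy(c(0.5, 1.516, 2.5), c(0, 1.0, 2.0))
  expect_equal(ds$delta_s, c(0.016, -0.016))
  g <- glance(ds)
  expect_equal(g$mean_s, 0)
  expect_equal(g$sd_s, 0.016 * sqrt(2))
  expect_equal(attr(ds, "kind"), "log_timing")
  # n events yield n-1 interval differences
  expect_equal(g$n, 2)
})

test_that("constant clock offsets cancel exactly in interval-based metrics", {
  x <- withr::with_seed(5, cumsum(runif(40, 0.5, 1.5)))
  y <- withr::with_seed(6, x + rnorm(40, 0, 0.004))
  base <- logging_inaccuracy(x, y)$delta_s
  for (shift in c(-3.7, 0.032, 120)) {
    # exact at any physical scale: differences below a nanosecond
    expect_lt(max(abs(logging_inaccuracy(x + shift, y)$delta_s - base)),
              1e-9)
    expect_lt(max(abs(logging_inaccuracy(x, y + shift)$delta_s - base)),
              1e-9)
    expect_lt(max(abs(trigger_jitter(x + shift, y)$delta_s -
                        trigger_jitter(x, y)$delta_s)), 1e-9)
  }
})

test_that("swapping streams negates every interval-difference value", {
  x <- withr::with_seed(7, cumsum(runif(30, 0.5, 1.5)))
  y <- withr::with_seed(8, x + rnorm(30, 0, 0.003))
  expect_equal(logging_inaccuracy(x, y)$delta_s,
               -logging_inaccuracy(y, x)$delta_s)
  expect_equal(trigger_delay(x, y)$delta_s, -trigger_delay(y, x)$delta_s)
})

test_that("identical streams give an all-zero series", {
  x <- cumsum(rep(1.1, 20))
  expect_true(all(logging_inaccuracy(x, x)$delta_s == 0))
  expect_true(all(trigger_jitter(x, x)$delta_s == 0))
  expect_true(all(trigger_delay(x, x)$delta_s == 0))
})

test_that("interval SD recovers sqrt(2) times the injected per-event jitter", {
  fx <- generate_experiment(
    experiment_plan(500, planned_durations = 0.2,
                    inter_event_interval = 0.3),
    corruption_spec(jitter_sd = 0.005), seed = 13
  )
  ds <- logging_inaccuracy(fx$truth, fx$log)
  target <- 0.005 * sqrt(2)
  expect_lt(abs(glance(ds)$sd_s - target) / target, 0.15)
  expect_lt(abs(glance(ds)$mean_s), 0.001)
})

test_that("duration deviation measures observed minus planned", {
  log <- tibble::tibble(
    event_index = 1:2, onset_s = c(0, 1),
    planned_duration_s = c(0.5, 0.5), event_class = "controlled"
  )
  photo <- pulse_seq(c(0, 1), offsets = c(0.5, 1.516))
  expect_equal(duration_deviation(photo, log)$delta_s, c(0, 0.016))

  no_off <- pulse_seq(c(0, 1))
  expect_error(duration_deviation(no_off, log), "onset_and_offset")
})

test_that("clean fixture yields zero duration deviation through the full pipeline", {
  fx <- clean_fixture(n = 8, with_responses = FALSE)
  fs <- 2000
  pulses <- parse_photodiode(synthesize_photodiode(fx$truth, fs = fs))
  paired <- pair_pulses_to_events(pulses, fx$log)
  dd <- duration_deviation(paired, fx$log)
  expect_lt(max(abs(dd$delta_s)), 1 / fs)
})

test_that("trigger jitter sees jitter but is blind to delays", {
  ds <- trigger_jitter(c(0.5, 1.5, 2.5), c(10.5, 11.52, 12.5))
  expect_equal(ds$delta_s, c(-0.02, 0.02))
  x <- cumsum(rep(0.9, 15))
  expect_lt(max(abs(trigger_jitter(x, x + 0.030)$delta_s)), 1e-12)
})

test_that("trigger delay recovers a constant delay exactly and flags drift", {
  expect_equal(trigger_delay(1.032, 1.000)$delta_s, 0.032)
  x <- cumsum(rep(1, 50))
  ds <- trigger_delay(x, x - 0.030)
  expect_equal(glance(ds)$mean_s, 0.030)
  expect_equal(glance(ds)$sd_s, 0)
  expect_equal(glance(ds)$n, 50)
  # linear drift diagnostic: 1 ms per second shows up as the slope
  drifted <- trigger_delay(x, x - 0.001 * x)
  expect_equal(attr(drifted, "drift_s_per_s"), 0.001, tolerance = 1e-9)
})

test_that("response timestamping inaccuracy mirrors the controlled-event metric", {
  fx <- generate_experiment(std_plan(300), corruption_spec(jitter_sd = 0.003),
                            seed = 17)
  ds <- response_inaccuracy(fx$press_truth, fx$log)
  expect_equal(attr(ds, "kind"), "response_timing")
  target <- 0.003 * sqrt(2)
  expect_lt(abs(glance(ds)$sd_s - target) / target, 0.2)

  # sign convention: physical intervals minus logged intervals
  logged <- c(1.0, 2.0)
  audio <- c(1.0, 1.990) # second press logged 10 ms late
  expect_equal(response_inaccuracy(audio, logged)$delta_s, -0.010)
})

test_that("summaries follow the n-1 SD convention with a low-n flag", {
  two <- delta_series(c(0.016, -0.016), kind = "log_timing")
  expect_equal(glance(two)$sd_s, abs(0.016) * sqrt(2))
  one <- delta_series(0.005, kind = "trigger_delay")
  g1 <- glance(one)
  expect_equal(g1$mean_s, 0.005)
  expect_equal(g1$sd_s, 0)
  expect_true(g1$low_n)
  zeros <- delta_series(rep(0, 10), kind = "log_timing")
  expect_equal(glance(zeros)$mean_s, 0)
  expect_equal(glance(zeros)$sd_s, 0)
  expect_error(glance(delta_series(numeric(0), kind = "log_timing")),
               "empty")
})

test_that("calibration status warns above the configured SD threshold", {
  good <- delta_series(withr::with_seed(1, rnorm(200, 0, 0.002)),
                       kind = "log_timing")
  bad <- delta_series(withr::with_seed(2, rnorm(200, 0, 0.02)),
                      kind = "log_timing")
  expect_equal(delta_summary(good)$status, "pass")
  expect_equal(delta_summary(bad)$status, "warn")
  expect_equal(delta_summary(bad, sd_warn_s = 0.1)$status, "pass")
})
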