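test_that("welch t matches hand evaluation and the pooled-t oracle", {
  expect_equal(welch_t(c(1, 2, 3), c(2, 3, 4)), -1.224745,
               tolerance = 1e-6)
  x <- c(4, 4, 4)
  expect_equal(welch_t(x, x), 0)

  # equal-variance case coincides with the pooled two-sample t
  a <- withr::with_seed(1, rnorm(40, 0, 2))
  b <- withr::with_seed(2, rnorm(40, 0.5, 2))
  pooled <- (mean(a) - mean(b)) /
    sqrt(((var(a) + var(b)) / 2) * (2 / 40))
  expect_equal(welch_t(a, b), pooled, tolerance = 1e-9)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("label shuffle preserves the label multiset and attenuates by 1 - p", {
  labs <- rep(c("a", "b"), each = 50)
  expect_identical(shuffle_labels(labs, 0, seed = 1), labs)
  full <- shuffle_labels(labs, 1, seed = 2)
  expect_equal(sum(full == "a"), 50)
  expect_equal(sum(full == "b"), 50)
  expect_identical(shuffle_labels(labs, 0.3, seed = 9),
                   shuffle_labels(labs, 0.3, seed = 9))

  # simulation check of the (1 - p) attenuation of the group difference
  n <- 10000
  p <- 0.4
  vals <- withr::with_seed(3, rnorm(2 * n))
  vals[(n + 1):(2 * n)] <- vals[(n + 1):(2 * n)] + 1
  labs2 <- rep(c(1, 2), each = n)
  diffs <- withr::with_seed(4, vapply(1:30, function(i) {
    sl <- shuffle_labels(labs2, p)
    mean(vals[sl == 2]) - mean(vals[sl == 1])
  }, 0))
  expect_equal(mean(diffs), 1 - p, tolerance = 0.02)
})

test_that("jitter injection leaves untouched configurations identical", {
  cfg <- sim_config("RT", theta = 0.3, n_trials = 50)
  tr <- simulate_rt_trials(cfg, seed = 5)
  expect_identical(inject_jitter(tr, 0, 16, seed = 1)$rt_measured_s,
                   tr$rt_measured_s)
  expect_identical(inject_jitter(tr, 0.5, 0, seed = 1)$rt_measured_s,
                   tr$rt_measured_s)
})

test_that("RT jitter of +/-32 ms on all trials adds 32^2 to the variance", {
  cfg <- sim_config("RT", theta = 0, n_trials = 40000,
                    rt = list(sd_s = 0.020))
  tr <- simulate_rt_trials(cfg, seed = 6)
  jt <- inject_jitter(tr, 1, 32, seed = 7)
  vif <- var(jt$rt_measured_s) / var(tr$rt_s)
  expect_equal(vif, (400 + 1024) / 400, tolerance = 0.03)
  # mean is untouched in expectation: +/- signs balance
  expect_lt(abs(mean(jt$rt_measured_s) - mean(tr$rt_s)), 5e-4)
})

test_that("P1 amplitudes match the analytic template mean when noise vanishes", {
  cfg <- sim_config("P1", theta = 0.2, n_trials = 4,
                    erp = list(noise_sd = 1e-12))
  wave <- simulate_erp_trials(cfg, return_epochs = TRUE, seed = 8)
  fast <- simulate_erp_trials(cfg, seed = 9)
  expect_equal(wave$amplitude, fast$amplitude, tolerance = 1e-6)
  # closed-form window integral of the template, by condition
  d_amp <- eventqa:::erp_diff_amp(cfg$erp, 0.2)
  det_a <- eventqa:::erp_measured_mean(cfg$erp, 0, -d_amp / 2)
  det_b <- eventqa:::erp_measured_mean(cfg$erp, 0, d_amp / 2)
  expect_equal(wave$amplitude, rep(c(det_a, det_b), each = 4),
               tolerance = 1e-6)
})

test_that("the waveform and distributional routes agree in spread", {
  cfg <- sim_config("P1", theta = 0, n_trials = 300)
  wave <- simulate_erp_trials(cfg, return_epochs = TRUE, seed = 10)
  fast <- simulate_erp_trials(cfg, seed = 11)
  sig <- eventqa:::erp_sigma_eff(cfg$erp)
  expect_equal(sd(wave$amplitude), sig, tolerance = 0.1)
  expect_equal(sd(fast$amplitude), sig, tolerance = 0.1)
})

test_that("uncorrupted measured amplitudes realize Cohen's d = theta", {
  cfg <- sim_config("P1", theta = 0.5, n_trials = 20000)
  tr <- simulate_erp_trials(cfg, seed = 12)
  a <- tr$amplitude[tr$condition == "a"]
  b <- tr$amplitude[tr$condition == "b"]
  d_hat <- (mean(b) - mean(a)) / sqrt((var(a) + var(b)) / 2)
  expect_equal(d_hat, 0.5, tolerance = 0.05)
})

test_that("huge jitter pushes the expected P1 amplitude to the noise mean", {
  cfg <- sim_config("P1", theta = 0.2, n_trials = 3000)
  tr <- simulate_erp_trials(cfg, seed = 13)
  jt <- inject_jitter(tr, 1, 400, seed = 14)
  sig <- eventqa:::erp_sigma_eff(cfg$erp)
  expect_lt(abs(mean(jt$amplitude)), 4 * sig / sqrt(nrow(jt)))
  expect_gt(abs(mean(tr$amplitude)), 10 * sig / sqrt(nrow(tr)))
})

test_that("epoch-shift remeasurement matches the template prediction", {
  cfg <- sim_config("P1", theta = 0, n_trials = 150,
                    erp = list(noise_sd = 1e-9))
  tr <- simulate_erp_trials(cfg, return_epochs = TRUE, seed = 15)
  jt <- inject_jitter(tr, 1, 16, seed = 16)
  pred <- vapply(jt$onset_error_s, function(e) {
    eventqa:::erp_measured_mean(cfg$erp, e, 0)
  }, 0)
  expect_equal(jt$amplitude, pred, tolerance = 1e-6)
  expect_true(all(abs(jt$onset_error_s) == 0.016))
})

test_that("null effect sizes produce centered t statistics", {
  cfg <- sim_config("RT", theta = 0, reps = 400, proportions = c(0, 0.2))
  sw <- run_sweep(cfg, seed = 17)
  # corruption must not manufacture an effect
  expect_true(all(abs(sw$mean_t) < 3 / sqrt(400)))
  expect_equal(sw$sd_t, c(1, 1), tolerance = 0.15)
})

test_that("an uncorrupted column matches the analytic two-sample expectation", {
  cfg_rt <- sim_config("RT", theta = 0.2, n_trials = 210, reps = 600,
                       proportions = 0)
  sw_rt <- run_sweep(cfg_rt, seed = 18)
  expect_equal(sw_rt$mean_t, 0.2 * sqrt(210 / 2), tolerance = 0.05)

  cfg_p1 <- sim_config("P1", theta = 0.5, n_trials = 500, reps = 200,
                       proportions = 0)
  sw_p1 <- run_sweep(cfg_p1, seed = 19)
  expect_equal(sw_p1$mean_t, 0.5 * sqrt(500 / 2), tolerance = 0.05)
})

test_that("sweeps are deterministic and non-increasing in shuffle proportion", {
  cfg <- sim_config("RT", theta = 0.4, reps = 400,
                    proportions = c(0, 0.1, 0.25, 0.4))
  a <- run_sweep(cfg, seed = 20)
  b <- run_sweep(cfg, seed = 20)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # attenuation monotonicity within 2 Monte-Carlo SEs
  se <- sqrt(a$sd_t[-1]^2 + a$sd_t[-4]^2) / sqrt(400)
  expect_true(all(diff(a$mean_t) <= 2 * se))
})

test_that("the significance boundary is the first sub-threshold grid cell", {
  mk <- function(mean_t) {
    structure(
      tibble::tibble(
        measure = "RT", corruption = "shuffle", theta = 0.2,
        jitter_ms = NA_real_,
        proportion = c(0.02, 0.05, 0.10, 0.15, 0.20),
        mean_t = mean_t, sd_t = 1, reps = 500, n_trials = 206
      ),
      threshold = 1.96, class = c("sweep_result", "tbl_df", "tbl",
                                  "data.frame")
    )
  }
  surviving <- mk(c(2.5, 2.4, 2.3, 2.2, 2.1))
  expect_true(is.na(significance_boundary(surviving)))

  crossing <- mk(c(2.5, 2.3, 2.0, 1.9, 1.7))
  expect_equal(significance_boundary(crossing), 0.15)
  # brute-force scan oracle
  oracle <- crossing$proportion[which(crossing$mean_t < 1.96)[1]]
  expect_equal(significance_boundary(crossing), oracle)
})

test_that("sweep heatmaps build as ggplot objects", {
  cfg <- sim_config("P1", theta = c(0.2, 0.5), reps = 30,
                    proportions = c(0.05, 0.4), corruption = "jitter",
                    jitter_ms = c(16, 32), n_trials = 60)
  sw <- run_sweep(cfg, seed = 21)
  p <- ggplot2::autoplot(sw)
  expect_s3_class(p, "ggplot")
  g <- glance(sw)
  expect_equal(nrow(g), 4)
})
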