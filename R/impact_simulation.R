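#' Configuration for the corruption-impact simulation
#'
#' Describes a two-condition single-trial experiment whose dependent measure
#' is either a P1 ERP amplitude (`"P1"`) or a reaction time (`"RT"`), with a
#' standardized effect size `theta` (Cohen's d of the uncorrupted measured
#' variable), and the corruption grid to sweep: label shuffling or
#' fixed-magnitude onset jitter applied to a proportion of trials.
#'
#' The default trial counts, RT noise SD and ERP template are calibrated
#' (see the tuning script in `scripts/` and the methods vignette) so that
#' the uncorrupted mean t equals `theta * sqrt(n/2)` and the corruption
#' sweeps reproduce the package's reference sensitivity pattern. They are
#' frozen here and should be treated as the simulation's study conditions.
#'
#' @param measure `"P1"` or `"RT"`.
#' @param theta Standardized effect size(s); may be a vector for a sweep.
#' @param n_trials Trials per condition; default 282 (P1) / 206 (RT),
#'   calibrated.
#' @param reps Monte-Carlo replicates per grid cell.
#' @param corruption `"shuffle"` or `"jitter"`.
#' @param proportions Fractions of trials corrupted (grid).
#' @param jitter_ms Jitter magnitudes in ms (grid; jitter corruption only).
#' @param threshold Significance threshold on the t statistic.
#' @param rt List: `mean_s`, `sd_s` (per-trial RT distribution, normal).
#' @param erp List: `srate` (Hz), `epoch` (s, c(min, max)), `window` (s,
#'   measurement window), `baseline` (s), `noise_sd` (per-sample white
#'   sensor noise, uV), `components` (data frame: `component`, `latency_s`,
#'   `width_s`, `amp_uv`), `diff_component` (which component carries the
#'   condition difference).
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' sim_config("RT", theta = 0.2, reps = 100)
sim_config <- function(measure = c("P1", "RT"),
                       theta = 0.2,
                       n_trials = NULL,
                       reps = 500,
                       corruption = c("shuffle", "jitter"),
                       proportions = c(2, 5, 10, 15, 20, 25, 30, 35, 40) / 100,
                       jitter_ms = c(2, 8, 16, 24, 32, 40),
                       threshold = 1.96,
                       rt = list(),
                       erp = list()) {
  measure <- match.arg(measure)
  corruption <- match.arg(corruption)
  if (any(theta < 0)) abort("`theta` must be >= 0.")
  assert_proportion(proportions, "proportions")
  if (any(jitter_ms < 0)) abort("`jitter_ms` must be >= 0.")
  stopifnot(reps >= 1)
  n_trials <- n_trials %||% if (measure == "P1") 281L else 206L

  rt_defaults <- list(mean_s = 0.400, sd_s = 0.0204)
  rt <- utils::modifyList(rt_defaults, rt)

  erp_defaults <- list(
    srate = 1000,
    epoch = c(-0.2, 0.5),
    window = c(0.09, 0.11),
    baseline = c(-0.1, 0),
    noise_sd = 10,
    components = data.frame(
      component = c("p1", "n1"),
      latency_s = c(0.1000, 0.1595),
      width_s = c(0.0060, 0.0269),
      amp_uv = c(1.650, -18.232)
    ),
    diff_component = "p1"
  )
  erp <- utils::modifyList(erp_defaults, erp)
  erp$components <- as.data.frame(erp$components)
  if (!erp$diff_component %in% erp$components$component) {
    abort("`diff_component` must name a row of `components`.")
  }
  if (erp$window[1] < erp$epoch[1] || erp$window[2] > erp$epoch[2] ||
      erp$baseline[1] < erp$epoch[1] || erp$baseline[2] > erp$epoch[2]) {
    abort("measurement and baseline windows must lie inside the epoch.")
  }

  structure(
    list(
      measure = measure, theta = theta, n_trials = as.integer(n_trials),
      reps = as.integer(reps), corruption = corruption,
      proportions = proportions, jitter_ms = jitter_ms,
      threshold = threshold, rt = rt, erp = erp
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %s, theta = %s, n = %d/condition, %s corruption, %d reps\n",
    x$measure, paste(x$theta, collapse = ", "), x$n_trials, x$corruption,
    x$reps
  ))
  invisible(x)
}

#' Read a simulation configuration from YAML
#'
#' Fields mirror [sim_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$erp$components)) {
    y$erp$components <- as.data.frame(y$erp$components)
  }
  do.call(sim_config, y)
}

# ---- ERP template machinery -------------------------------------------------

epoch_times <- function(erp) {
  seq(erp$epoch[1], erp$epoch[2], by = 1 / erp$srate)
}

window_index <- function(times, win) {
  which(times >= win[1] - 1e-9 & times <= win[2] + 1e-9)
}

# SD of the measured amplitude induced by white per-sample sensor noise:
# the window mean minus baseline mean of iid N(0, noise_sd) samples.
erp_sigma_eff <- function(erp) {
  tt <- epoch_times(erp)
  n_win <- length(window_index(tt, erp$window))
  n_base <- length(window_index(tt, erp$baseline))
  erp$noise_sd * sqrt(1 / n_win + 1 / n_base)
}

# Sum-of-Gaussian-bumps template evaluated at template times `t` (seconds
# after true stimulus onset). `extra_amp` is added to the amplitude of the
# condition-difference component.
erp_template <- function(t, erp, extra_amp = 0) {
  comps <- erp$components
  v <- numeric(length(t))
  for (k in seq_len(nrow(comps))) {
    a <- comps$amp_uv[k] +
      if (comps$component[k] == erp$diff_component) extra_amp else 0
    v <- v + a * exp(-((t - comps$latency_s[k])^2) /
                       (2 * comps$width_s[k]^2))
  }
  v
}

# Peak-amplitude condition difference that yields Cohen's d = theta on the
# measured (window-mean, baseline-corrected) amplitude.
erp_diff_amp <- function(erp, theta) {
  tt <- epoch_times(erp)
  iw <- window_index(tt, erp$window)
  ib <- window_index(tt, erp$baseline)
  k <- which(erp$components$component == erp$diff_component)
  unit <- exp(-((tt - erp$components$latency_s[k])^2) /
                (2 * erp$components$width_s[k]^2))
  gain <- mean(unit[iw]) - mean(unit[ib])
  theta * erp_sigma_eff(erp) / gain
}

# Deterministic part of the measured amplitude for one condition under an
# onset-logging error eps (epoch extracted eps seconds after the true
# onset, so the window samples the template at t + eps). Uses the same
# discrete sample grid as the materialized waveform route, so the two
# routes agree exactly at zero noise.
erp_measured_mean <- function(erp, eps = 0, extra_amp = 0) {
  tt <- epoch_times(erp)
  iw <- window_index(tt, erp$window)
  ib <- window_index(tt, erp$baseline)
  mean(erp_template(tt[iw] + eps, erp, extra_amp)) -
    mean(erp_template(tt[ib] + eps, erp, extra_amp))
}

#' Simulate single-trial P1 amplitudes
#'
#' Each trial is conceptually a waveform: the sum of Gaussian-bump ERP
#' components plus white sensor noise, epoch-locked to the *logged* onset.
#' The measured amplitude is the mean of the baseline-corrected signal
#' inside the measurement window. The condition difference is carried by
#' the `diff_component` amplitude, scaled so the uncorrupted measured
#' amplitudes have Cohen's d equal to `theta`.
#'
#' With `return_epochs = FALSE` (default) the measured amplitude is drawn
#' directly from its exact distribution -- deterministic template window
#' mean plus a Gaussian noise functional with SD
#' `noise_sd * sqrt(1/n_window + 1/n_baseline)` -- which is identical in
#' distribution to materializing every epoch sample and averaging, and is
#' what makes large Monte-Carlo sweeps affordable. With
#' `return_epochs = TRUE` the full epochs are materialized (samples x
#' trials matrix in attribute `"epochs"`) and measured literally; tests
#' cross-check the two routes.
#'
#' @param config A [sim_config()] with `measure = "P1"`; `config$theta`
#'   must be a single value here.
#' @param onset_errors Per-trial onset-logging error in seconds (length
#'   `2 * n_trials`), as injected by [inject_jitter()]; default all zero.
#' @param return_epochs Materialize waveforms (slow, exact-literal route).
#' @param seed RNG seed.
#' @return Tibble with `trial`, `condition` (`"a"`/`"b"`), `onset_error_s`,
#'   `amplitude`; attributes `config` and optionally `epochs`.
#' @export
simulate_erp_trials <- function(config, onset_errors = NULL,
                                return_epochs = FALSE, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), config$measure == "P1",
            length(config$theta) == 1L)
  erp <- config$erp
  n <- config$n_trials
  N <- 2L * n
  onset_errors <- onset_errors %||% rep(0, N)
  stopifnot(length(onset_errors) == N)
  condition <- rep(c("a", "b"), each = n)
  d_amp <- erp_diff_amp(erp, config$theta)
  extra <- ifelse(condition == "b", d_amp / 2, -d_amp / 2)

  with_seed_(seed, {
    if (return_epochs) {
      tt <- epoch_times(erp)
      iw <- window_index(tt, erp$window)
      ib <- window_index(tt, erp$baseline)
      epochs <- matrix(0, nrow = length(tt), ncol = N)
      for (j in seq_len(N)) {
        epochs[, j] <- erp_template(tt + onset_errors[j], erp, extra[j]) +
          rnorm(length(tt), 0, erp$noise_sd)
      }
      amplitude <- colMeans(epochs[iw, , drop = FALSE]) -
        colMeans(epochs[ib, , drop = FALSE])
    } else {
      key <- paste(condition, signif(onset_errors, 12))
      uniq <- !duplicated(key)
      det_map <- setNames(
        mapply(function(e, x) erp_measured_mean(erp, e, x),
               onset_errors[uniq], extra[uniq]),
        key[uniq]
      )
      amplitude <- unname(det_map[key]) +
        rnorm(N, 0, erp_sigma_eff(erp))
    }
    out <- tibble(
      trial = seq_len(N), condition = condition,
      onset_error_s = onset_errors, amplitude = amplitude
    )
    attr(out, "config") <- config
    if (return_epochs) attr(out, "epochs") <- epochs
    class(out) <- c("erp_trials", class(out))
    out
  })
}

#' Simulate single-trial reaction times
#'
#' Normal per-condition reaction times with standardized mean difference
#' `theta`; the measured RT is the true RT plus any logged-onset error
#' (a stimulus logged late makes the response look fast, and vice versa).
#'
#' @param config A [sim_config()] with `measure = "RT"`; single `theta`.
#' @param seed RNG seed.
#' @return Tibble with `trial`, `condition`, `rt_s`, `onset_error_s`,
#'   `rt_measured_s`.
#' @export
simulate_rt_trials <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), config$measure == "RT",
            length(config$theta) == 1L)
  n <- config$n_trials
  N <- 2L * n
  condition <- rep(c("a", "b"), each = n)
  d <- config$theta * config$rt$sd_s
  with_seed_(seed, {
    rt_s <- rnorm(N, config$rt$mean_s, config$rt$sd_s) +
      ifelse(condition == "b", d, 0)
    out <- tibble(
      trial = seq_len(N), condition = condition, rt_s = rt_s,
      onset_error_s = 0, rt_measured_s = rt_s
    )
    attr(out, "config") <- config
    class(out) <- c("rt_trials", class(out))
    out
  })
}

#' Shuffle condition labels on a random subset of trials
#'
#' `round(proportion * n)` trials are selected at random and their labels
#' randomly permuted within the subset, so the overall label multiset (and
#' the group sizes) are preserved exactly while the selected trials carry
#' no condition information in expectation.
#'
#' @param labels Vector of condition labels.
#' @param proportion Fraction of trials whose labels are shuffled.
#' @param seed RNG seed.
#' @return Labels vector of the same length and multiset.
#' @export
#' @examples
#' shuffle_labels(rep(c("a", "b"), 5), proportion = 0.4, seed = 1)
shuffle_labels <- function(labels, proportion, seed = NULL) {
  assert_proportion(proportion, "proportion")
  with_seed_(seed, {
    m <- round(proportion * length(labels))
    if (m >= 2) {
      sel <- sample.int(length(labels), m)
      labels[sel] <- labels[sel][sample.int(m)]
    }
    labels
  })
}

# Per-trial onset-error vector: +/- magnitude on a random subset of size
# round(proportion * n), zero elsewhere. Shared by inject_jitter() and the
# sweep engine so the corruption semantics have a single implementation.
jitter_errors <- function(n, proportion, magnitude_s) {
  err <- numeric(n)
  m <- round(proportion * n)
  if (m >= 1 && magnitude_s > 0) {
    sel <- sample.int(n, m)
    err[sel] <- magnitude_s * sample(c(-1, 1), m, replace = TRUE)
  }
  err
}

#' Inject fixed-magnitude onset jitter into simulated trials
#'
#' A random subset of trials (fraction `proportion`) receives an
#' onset-logging error of +/- `magnitude_ms` (random sign). For RT trials
#' the error adds to the measured RT. For P1 trials the epoch shifts
#' relative to the waveform: when the trials carry materialized epochs the
#' measurement window is re-extracted at the shifted position; otherwise
#' the amplitude is re-drawn from its exact distribution at the shifted
#' template position.
#'
#' @param trials Output of [simulate_erp_trials()] or
#'   [simulate_rt_trials()].
#' @param proportion Fraction of trials jittered.
#' @param magnitude_ms Jitter magnitude in milliseconds.
#' @param seed RNG seed.
#' @return The trials tibble with `onset_error_s` and the measured variable
#'   updated.
#' @export
inject_jitter <- function(trials, proportion, magnitude_ms, seed = NULL) {
  assert_proportion(proportion, "proportion")
  if (magnitude_ms < 0) abort("`magnitude_ms` must be >= 0.")
  config <- attr(trials, "config")
  N <- nrow(trials)
  with_seed_(seed, {
    err <- jitter_errors(N, proportion, magnitude_ms / 1000)
    trials$onset_error_s <- trials$onset_error_s + err
    if (inherits(trials, "rt_trials")) {
      trials$rt_measured_s <- trials$rt_measured_s + err
    } else {
      hit <- which(err != 0)
      if (length(hit) > 0) {
        epochs <- attr(trials, "epochs")
        erp <- config$erp
        d_amp <- erp_diff_amp(erp, config$theta)
        extra <- ifelse(trials$condition == "b", d_amp / 2, -d_amp / 2)
        if (!is.null(epochs)) {
          tt <- epoch_times(erp)
          iw <- window_index(tt, erp$window)
          ib <- window_index(tt, erp$baseline)
          for (j in hit) {
            sh <- round(trials$onset_error_s[j] * erp$srate)
            trials$amplitude[j] <- mean(epochs[iw + sh, j]) -
              mean(epochs[ib + sh, j])
          }
        } else {
          sig <- erp_sigma_eff(erp)
          for (j in hit) {
            trials$amplitude[j] <-
              erp_measured_mean(erp, trials$onset_error_s[j], extra[j]) +
              rnorm(1, 0, sig)
          }
        }
      }
    }
    trials
  })
}

#' Welch's two-sample t statistic
#'
#' Unequal-variance two-sample t. The degenerate case (both groups constant
#' with equal means) returns 0 by convention.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return The t statistic (a bare number).
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(2, 3, 4))
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("each sample needs n >= 2.")
  se2 <- var(x) / length(x) + var(y) / length(y)
  num <- mean(x) - mean(y)
  if (se2 == 0) {
    if (num == 0) return(0)
    abort("zero variance with unequal means: t is undefined.")
  }
  num / sqrt(se2)
}

# ---- sweep engine -----------------------------------------------------------

# Mean and SD of the Welch t over `reps` corrupted replicates of one grid
# cell. Works on bare vectors for speed; corruption semantics come from
# shuffle_labels() / jitter_errors().
sweep_cell <- function(config, theta, proportion, magnitude_s, reps) {
  n <- config$n_trials
  N <- 2L * n
  i1 <- seq_len(n)
  i2 <- (n + 1L):N
  lab0 <- rep(1:2, each = n)
  shuffle <- config$corruption == "shuffle"

  if (config$measure == "RT") {
    sdv <- config$rt$sd_s
    d <- theta * sdv
    base_det <- c(0, d)
  } else {
    erp <- config$erp
    sdv <- erp_sigma_eff(erp)
    d_amp <- erp_diff_amp(erp, theta)
    shifts <- c(0, magnitude_s, -magnitude_s)
    det <- matrix(0, nrow = 2, ncol = 3) # condition x {0, +mag, -mag}
    for (ci in 1:2) {
      extra <- if (ci == 2) d_amp / 2 else -d_amp / 2
      for (si in 1:3) {
        det[ci, si] <- erp_measured_mean(erp, shifts[si], extra)
      }
    }
    base_det <- det[, 1]
  }

  t_vals <- numeric(reps)
  for (r in seq_len(reps)) {
    if (shuffle) {
      y <- base_det[lab0] + rnorm(N, 0, sdv)
      lab <- shuffle_labels(lab0, proportion)
      g1 <- y[lab == 1L]
      g2 <- y[lab == 2L]
    } else {
      err <- jitter_errors(N, proportion, magnitude_s)
      if (config$measure == "RT") {
        y <- base_det[lab0] + rnorm(N, 0, sdv) + err
      } else {
        si <- 1L + (err > 0) + 2L * (err < 0)
        y <- det[cbind(lab0, si)] + rnorm(N, 0, sdv)
      }
      g1 <- y[i1]
      g2 <- y[i2]
    }
    t_vals[r] <- welch_t(g2, g1)
  }
  c(mean_t = mean(t_vals), sd_t = sd(t_vals))
}

#' Sweep the corruption grid
#'
#' For every grid cell (effect size x corruption proportion, and jitter
#' magnitude for the jitter corruption) simulates `reps` independent
#' corrupted datasets, computes Welch's t across trials for each, and
#' records the mean and SD of the t statistic. Deterministic under a fixed
#' seed.
#'
#' @param config A [sim_config()]; `config$theta` may be a vector.
#' @param seed RNG seed for the whole sweep.
#' @return A tibble of class `sweep_result`: `measure`, `corruption`,
#'   `theta`, `jitter_ms` (`NA` for shuffle), `proportion`, `mean_t`,
#'   `sd_t`, `reps`, `n_trials`; significance threshold in
#'   `attr(, "threshold")`.
#' @export
#' @examples
#' cfg <- sim_config("RT", theta = 0.2, reps = 50,
#'                   proportions = c(0.05, 0.4))
#' run_sweep(cfg, seed = 1)
run_sweep <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  grid <- if (config$corruption == "shuffle") {
    tidyr::expand_grid(theta = config$theta, jitter_ms = NA_real_,
                       proportion = config$proportions)
  } else {
    tidyr::expand_grid(theta = config$theta, jitter_ms = config$jitter_ms,
                       proportion = config$proportions)
  }
  with_seed_(seed, {
    stats_m <- purrr::pmap(grid, function(theta, jitter_ms, proportion) {
      sweep_cell(config, theta, proportion,
                 if (is.na(jitter_ms)) 0 else jitter_ms / 1000,
                 config$reps)
    })
  })
  out <- dplyr::bind_cols(
    tibble(measure = config$measure, corruption = config$corruption),
    grid,
    dplyr::bind_rows(purrr::map(stats_m, as.list))
  )
  out$reps <- config$reps
  out$n_trials <- config$n_trials
  structure(out, threshold = config$threshold,
            class = c("sweep_result", class(out)))
}

#' Smallest corruption proportion abolishing the effect
#'
#' Scans one column of a sweep (fixed effect size and, for jitter, fixed
#' magnitude) in increasing proportion order and returns the smallest grid
#' proportion whose mean t statistic falls below the significance
#' threshold, or `NA` if the effect survives the whole grid.
#'
#' @param sweep A [run_sweep()] result.
#' @param theta Effect size to select (may be omitted if unique).
#' @param jitter_ms Jitter magnitude to select (jitter sweeps).
#' @param threshold Override the sweep's threshold.
#' @return The boundary proportion as a fraction, or `NA_real_`.
#' @export
significance_boundary <- function(sweep, theta = NULL, jitter_ms = NULL,
                                  threshold = NULL) {
  threshold <- threshold %||% attr(sweep, "threshold") %||% 1.96
  rows <- sweep
  if (!is.null(theta)) rows <- rows[rows$theta == theta, , drop = FALSE]
  if (!is.null(jitter_ms)) {
    rows <- rows[!is.na(rows$jitter_ms) & rows$jitter_ms == jitter_ms, ,
                 drop = FALSE]
  }
  if (nrow(rows) == 0) abort("no sweep cells match the selection.")
  if (anyDuplicated(rows$proportion) > 0) {
    abort("selection is ambiguous: fix `theta` (and `jitter_ms`).")
  }
  rows <- rows[order(rows$proportion), , drop = FALSE]
  below <- which(rows$mean_t < threshold)
  if (length(below) == 0) NA_real_ else rows$proportion[below[1]]
}

#' @export
glance.sweep_result <- function(x, ...) {
  key <- dplyr::distinct(x[, c("measure", "corruption", "theta",
                               "jitter_ms")])
  key$boundary_proportion <- purrr::map2_dbl(
    key$theta, key$jitter_ms,
    function(th, jm) {
      significance_boundary(
        x, theta = th,
        jitter_ms = if (is.na(jm)) NULL else jm
      )
    }
  )
  key
}

#' @export
tidy.sweep_result <- function(x, ...) as_tibble(unclass(x))

#' Heatmap of a corruption sweep
#'
#' Mean t statistic as a function of effect size and corruption proportion,
#' color-diverging around the significance threshold (blue below, orange
#' above), faceted by jitter magnitude where applicable.
#'
#' @param object A [run_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  thr <- attr(object, "threshold") %||% 1.96
  df <- as_tibble(unclass(object))
  p <- ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = factor(.data$theta),
      y = factor(100 * .data$proportion),
      fill = .data$mean_t
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      midpoint = thr, low = "#2166ac", mid = "white", high = "#e08214",
      name = "mean t"
    ) +
    ggplot2::labs(
      x = "effect size (Cohen's d)",
      y = "% of trials corrupted",
      title = sprintf("%s, %s corruption (threshold t = %.2f)",
                      df$measure[1], df$corruption[1], thr)
    ) +
    ggplot2::theme_minimal()
  if (!all(is.na(df$jitter_ms))) {
    p <- p + ggplot2::facet_wrap(~jitter_ms, labeller = ggplot2::label_both)
  }
  p
}
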