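#' Generate a synthetic experiment with known corruptions
#'
#' Builds the ground-truth physical timeline of an experiment from a plan and
#' an event log as the experimental software would have written it, with the
#' requested defects injected. Because every injected quantity is returned
#' alongside the log, all timing and content metrics in the package can be
#' validated by parameter recovery without any recorded data.
#'
#' Timing convention: a positive `clock_delay` means the physical realization
#' of an event occurs `clock_delay` seconds *after* its logged timestamp (the
#' usual display-latency situation), so `ground truth - logged = clock_delay`
#' and the delay estimators recover `+clock_delay`.
#'
#' @param plan An [experiment_plan()].
#' @param corruption A [corruption_spec()].
#' @param seed RNG seed; defaults to `corruption$seed`.
#' @return A list of class `eventqa_experiment` with elements
#'   * `log`: tibble event log (`event_index`, `onset_s`, `planned_onset_s`,
#'     `planned_duration_s`, factor columns, `event_class`, `response_key`);
#'   * `truth`: [pulse_seq()] of true stimulus onsets/offsets;
#'   * `press_truth`: [pulse_seq()] of true key-press times (or `NULL`);
#'   * `injected`: the realized corruptions (jitter draws, mislabeled rows,
#'     dropped rows) for parameter-recovery tests;
#'   * `plan`, `corruption`: the inputs.
#' @export
#' @examples
#' fx <- generate_experiment(experiment_plan(6), corruption_spec(), seed = 1)
#' fx$log
generate_experiment <- function(plan, corruption = corruption_spec(),
                                seed = NULL) {
  stopifnot(inherits(plan, "experiment_plan"),
            inherits(corruption, "corruption_spec"))
  seed <- seed %||% corruption$seed
  with_seed_(seed, {
    n <- plan$n_events
    durs <- plan$planned_durations
    gaps <- plan$inter_event_interval
    onsets <- plan$t0 + cumsum(c(0, head(durs + gaps, -1)))
    offsets <- onsets + durs

    # balanced full cross of the declared factors, order randomized
    grid <- expand.grid(plan$factors, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    idx <- rep_len(seq_len(nrow(grid)), n)[sample.int(n)]
    labels <- as_tibble(grid[idx, , drop = FALSE])

    stim <- tibble(
      true_time_s = onsets,
      planned_onset_s = onsets,
      planned_duration_s = durs,
      event_class = "controlled",
      response_key = NA_character_
    )
    stim <- dplyr::bind_cols(stim, labels)

    press_truth <- NULL
    rows <- stim
    if (!is.null(plan$response_plan)) {
      rp <- plan$response_plan
      rp_idx <- rep_len(seq_len(nrow(rp)), n)
      press_list <- purrr::map(seq_len(n), function(e) {
        r <- rp[rp_idx[e], ]
        if (r$presses == 0) return(NULL)
        tibble(
          true_time_s = offsets[e] + 0.35 + 0.15 * (seq_len(r$presses) - 1),
          planned_onset_s = NA_real_,
          planned_duration_s = NA_real_,
          event_class = "uncontrolled",
          response_key = r$key
        )
      })
      presses <- dplyr::bind_rows(press_list)
      if (nrow(presses) > 0) {
        press_truth <- pulse_seq(presses$true_time_s, source = "microphone")
        for (f in names(plan$factors)) presses[[f]] <- NA_character_
        rows <- dplyr::bind_rows(stim, presses)
      }
    }
    rows <- dplyr::arrange(rows, .data$true_time_s)
    rows$event_index <- seq_len(nrow(rows))

    # clock model: logged = truth - clock_delay + noise
    n_rows <- nrow(rows)
    jitter <- if (corruption$jitter_sd > 0) {
      rnorm(n_rows, 0, corruption$jitter_sd)
    } else {
      rep(0, n_rows)
    }
    if (corruption$jitter_magnitude > 0 && corruption$jitter_proportion > 0) {
      m <- round(corruption$jitter_proportion * n_rows)
      if (m > 0) {
        sel <- sample.int(n_rows, m)
        jitter[sel] <- jitter[sel] +
          corruption$jitter_magnitude * sample(c(-1, 1), m, replace = TRUE)
      }
    }
    rows$onset_s <- rows$true_time_s - corruption$clock_delay + jitter

    bad <- which(diff(rows$onset_s) <= 0)
    if (length(bad) > 0) {
      abort(sprintf(
        "corruption makes logged onsets non-monotonic at event %d.",
        rows$event_index[bad[1] + 1]
      ))
    }

    label_rows <- tibble(
      event_index = integer(), field = character(),
      original = character(), corrupted = character()
    )
    if (corruption$label_errors > 0) {
      swappable <- names(plan$factors)[
        purrr::map_int(plan$factors, length) >= 2
      ]
      if (length(swappable) == 0) {
        abort("label_errors requested but no factor has >= 2 levels.")
      }
      ctrl <- which(rows$event_class == "controlled")
      if (corruption$label_errors > length(ctrl)) {
        abort("label_errors exceeds the number of controlled events.")
      }
      err_rows <- sort(sample(ctrl, corruption$label_errors))
      for (i in err_rows) {
        f <- if (length(swappable) == 1) swappable else sample(swappable, 1)
        orig <- rows[[f]][i]
        rows[[f]][i] <- sample(setdiff(plan$factors[[f]], orig), 1)
        label_rows <- dplyr::bind_rows(label_rows, tibble(
          event_index = rows$event_index[i], field = f,
          original = orig, corrupted = rows[[f]][i]
        ))
      }
    }

    dropped <- integer()
    if (corruption$drop_events > 0) {
      if (corruption$drop_events >= n_rows) {
        abort("drop_events would empty the log.")
      }
      dropped <- sort(sample.int(n_rows, corruption$drop_events))
      rows <- rows[-dropped, ]
    }

    log <- dplyr::select(
      rows, "event_index", "onset_s", "planned_onset_s",
      "planned_duration_s", dplyr::all_of(names(plan$factors)),
      "event_class", "response_key"
    )
    attr(log, "factors") <- names(plan$factors)
    attr(log, "true_time_s") <- rows$true_time_s

    structure(
      list(
        log = log,
        truth = pulse_seq(onsets, offsets = offsets, source = "truth"),
        press_truth = press_truth,
        injected = list(
          jitter_s = jitter,
          label_error_rows = label_rows,
          dropped_rows = dropped
        ),
        plan = plan,
        corruption = corruption
      ),
      class = "eventqa_experiment"
    )
  })
}

#' @export
print.eventqa_experiment <- function(x, ...) {
  cat(sprintf(
    "<eventqa_experiment> %d log rows (%d controlled), %d true events\n",
    nrow(x$log), sum(x$log$event_class == "controlled"), nrow(x$truth)
  ))
  invisible(x)
}

#' Synthesize a photodiode luminance trace
#'
#' Emulates the standard test-square protocol: a corner square flashes to
#' white for a brief pulse at each event onset (and, under the default
#' scheme, again at each event offset) and stays black otherwise. The trace
#' is a low baseline with rectangular high pulses plus optional Gaussian
#' sensor noise.
#'
#' @param truth A [pulse_seq()] (or numeric onset vector) of true event
#'   times. Offsets are required for `scheme = "onset_and_offset"`.
#' @param fs Sampling rate in Hz; must exceed `2 / pulse_width`.
#' @param pulse_width Width of each flash in seconds. Default is one frame at
#'   60 Hz (16.7 ms), the shortest flash a typical display can show.
#' @param noise_sd SD of additive Gaussian noise (luminance units).
#' @param scheme `"onset_and_offset"` (flash at both, the default) or
#'   `"onset_only"`.
#' @param baseline,amplitude Low level and pulse height (luminance units).
#' @param start_time Time of the first sample in seconds.
#' @param pad Trailing silence after the last pulse, seconds.
#' @param seed RNG seed for the noise.
#' @return An [analog_trace()] tagged `"photodiode"`.
#' @export
#' @examples
#' tr <- synthesize_photodiode(pulse_seq(0.1), fs = 1000, pulse_width = 0.02,
#'                             scheme = "onset_only")
synthesize_photodiode <- function(truth, fs = 2000,
                                  pulse_width = 1 / 60,
                                  noise_sd = 0,
                                  scheme = c("onset_and_offset", "onset_only"),
                                  baseline = 0, amplitude = 1,
                                  start_time = 0, pad = 0.05,
                                  seed = NULL) {
  scheme <- match.arg(scheme)
  assert_positive(fs, "fs")
  assert_positive(pulse_width, "pulse_width")
  if (fs <= 2 / pulse_width) {
    abort("`fs` must exceed 2 / pulse_width to resolve the pulses.")
  }
  if (is.numeric(truth)) truth <- pulse_seq(truth, source = "truth")
  flash <- truth$onset_s
  if (scheme == "onset_and_offset") {
    if (is.null(truth[["offset_s"]])) {
      abort("scheme 'onset_and_offset' needs offsets in `truth`.")
    }
    flash <- sort(c(truth$onset_s, truth$offset_s))
  }
  if (length(flash) > 1) {
    collide <- which(diff(flash) < pulse_width)
    if (length(collide) > 0) {
      abort(sprintf(
        "overlapping pulses at flash indices: %s",
        paste(collide, collapse = ", ")
      ))
    }
  }
  t_end <- if (length(flash) > 0) max(flash) + pulse_width + pad else
    start_time + pad
  n <- max(1L, ceiling((t_end - start_time) * fs))
  values <- rep(baseline, n)
  for (s in flash) {
    k0 <- ceiling((s - start_time) * fs + 1 - 1e-9)
    k1 <- ceiling((s + pulse_width - start_time) * fs + 1 - 1e-9) - 1L
    k0 <- max(k0, 1L); k1 <- min(k1, n)
    if (k1 >= k0) values[k0:k1] <- baseline + amplitude
  }
  if (noise_sd > 0) {
    values <- with_seed_(seed, values + rnorm(n, 0, noise_sd))
  }
  analog_trace(values, fs = fs, start_time = start_time,
               source = "photodiode")
}

#' Synthesize a keypress audio recording
#'
#' Emulates a contact microphone placed next to the response device:
#' near-silence (a low Gaussian noise floor) with a short broadband burst
#' starting at each press time.
#'
#' @param press_times A [pulse_seq()] or numeric vector of true press times
#'   in seconds; presses must be separated by more than `click_duration`.
#' @param fs Sampling rate in Hz.
#' @param click_duration Burst length in seconds.
#' @param snr Amplitude ratio of burst RMS to noise floor RMS.
#' @param noise_floor RMS of the silence noise floor.
#' @param start_time,pad As in [synthesize_photodiode()].
#' @param seed RNG seed.
#' @return An [analog_trace()] tagged `"microphone"`.
#' @export
synthesize_keypress_audio <- function(press_times, fs = 44100,
                                      click_duration = 0.01, snr = 10,
                                      noise_floor = 0.005,
                                      start_time = 0, pad = 0.1,
                                      seed = NULL) {
  assert_positive(fs, "fs")
  assert_positive(click_duration, "click_duration")
  assert_positive(snr, "snr")
  if (inherits(press_times, "pulse_seq")) press_times <- press_times$onset_s
  if (length(press_times) > 1) {
    collide <- which(diff(press_times) <= click_duration)
    if (length(collide) > 0) {
      abort(sprintf(
        "presses closer than click_duration at indices: %s",
        paste(collide, collapse = ", ")
      ))
    }
  }
  t_end <- if (length(press_times) > 0) {
    max(press_times) + click_duration + pad
  } else {
    start_time + pad
  }
  n <- max(1L, ceiling((t_end - start_time) * fs))
  with_seed_(seed, {
    values <- rnorm(n, 0, noise_floor)
    for (s in press_times) {
      k0 <- max(1L, ceiling((s - start_time) * fs + 1 - 1e-9))
      k1 <- min(n, ceiling((s + click_duration - start_time) * fs + 1 - 1e-9) - 1L)
      if (k1 >= k0) {
        values[k0:k1] <- values[k0:k1] +
          rnorm(k1 - k0 + 1, 0, snr * noise_floor)
      }
    }
    analog_trace(values, fs = fs, start_time = start_time,
                 source = "microphone")
  })
}

#' Synthesize a peripheral trigger stream
#'
#' One timestamped code per true event, on the peripheral's clock. A positive
#' `delay` means the physical event occurs `delay` seconds after its trigger
#' timestamp, so the timestamp-difference delay estimator
#' ([trigger_delay()], physical minus trigger) recovers `+delay`.
#'
#' @param truth A [pulse_seq()] or numeric vector of true event times.
#' @param codes Trigger code per event (character or integer).
#' @param delay Constant clock offset in seconds (see above).
#' @param jitter_sd SD in seconds of per-trigger Gaussian timing noise.
#' @param seed RNG seed.
#' @return A tibble with columns `timestamp_s`, `code`.
#' @export
#' @examples
#' synthesize_triggers(c(1.0, 2.0), codes = c("face", "object"),
#'                     delay = 0.030)
synthesize_triggers <- function(truth, codes, delay = 0, jitter_sd = 0,
                                seed = NULL) {
  if (inherits(truth, "pulse_seq")) truth <- truth$onset_s
  if (length(codes) != length(truth)) {
    abort("need exactly one code per truth event.")
  }
  if (jitter_sd < 0) abort("`jitter_sd` must be >= 0.")
  noise <- if (jitter_sd > 0) {
    with_seed_(seed, rnorm(length(truth), 0, jitter_sd))
  } else {
    rep(0, length(truth))
  }
  tibble(timestamp_s = truth - delay + noise, code = codes)
}
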