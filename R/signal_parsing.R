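#' Binarize an analog trace
#'
#' First stage of the pulse-extraction pipeline: every sample at or above the
#' threshold maps to 1 ("on"), everything below to 0 ("off"). The automatic
#' threshold is the midpoint of the 1st and 99th percentiles of the trace, a
#' robust mid-range that tolerates occasional outliers.
#'
#' @param trace An [analog_trace()] (or numeric vector).
#' @param threshold Numeric threshold, or `"auto"`.
#' @return A tibble of class `binarized_trace` with columns `time_s`, `on`
#'   (integer 0/1); sampling metadata is preserved as attributes.
#' @export
#' @examples
#' binarize(analog_trace(c(0, 0, 5, 5, 0), fs = 1000), threshold = 2.5)$on
binarize <- function(trace, threshold = "auto") {
  if (is.numeric(trace) && !inherits(trace, "analog_trace")) {
    trace <- analog_trace(trace, fs = 1)
  }
  v <- trace$value
  if (identical(threshold, "auto")) {
    q <- stats::quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
    if (diff(q) <= 0 || isTRUE(all.equal(q[1], q[2]))) {
      abort("cannot separate on/off states: trace is constant.")
    }
    threshold <- mean(q)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  out <- tibble(time_s = trace$time_s, on = as.integer(v >= threshold))
  structure(out,
    fs = trace_fs(trace), start_time = trace_start(trace),
    threshold = threshold, source = attr(trace, "source"),
    class = c("binarized_trace", class(out))
  )
}

#' Locate state transitions in a binarized signal
#'
#' Computes the discrete difference of the 0/1 sequence and stamps an onset
#' wherever the difference is +1 and an offset wherever it is -1. The
#' transition between samples n and n+1 is stamped at sample n+1 (the first
#' sample of the new state), at time `start_time + (n+1-1)/fs`. Transitions
#' closer than `refractory` seconds to the previous accepted transition are
#' discarded as threshold chatter; accepted transitions must alternate in
#' polarity, so a pulse whose offset falls inside the refractory window keeps
#' its onset and takes the next valid offset.
#'
#' @param x A `binarized_trace` from [binarize()], or a 0/1 vector.
#' @param fs,start_time Sampling metadata; taken from `x` when it is a
#'   `binarized_trace`.
#' @param refractory Minimum separation in seconds between accepted
#'   transitions. Default 0 (every transition kept); the photodiode
#'   pipeline [parse_photodiode()] defaults to 2 samples to suppress
#'   threshold chatter.
#' @param source Source tag for the result.
#' @return A [pulse_seq()]; empty input or no transitions yield zero rows.
#' @export
#' @examples
#' detect_transitions(c(0, 0, 1, 1, 0, 0, 1, 0), fs = 1000)
detect_transitions <- function(x, fs = NULL, start_time = NULL,
                               refractory = NULL, source = NULL) {
  if (inherits(x, "binarized_trace")) {
    fs <- fs %||% attr(x, "fs")
    start_time <- start_time %||% attr(x, "start_time")
    source <- source %||% attr(x, "source")
    x <- x$on
  }
  fs <- fs %||% abort("`fs` is required for plain vector input.")
  start_time <- start_time %||% 0
  refractory <- refractory %||% 0
  source <- source %||% "photodiode"
  if (!all(x %in% c(0L, 1L))) abort("input must be binary (0/1).")

  d <- diff(x)
  idx <- which(d != 0) + 1L # first sample of the new state
  times <- start_time + (idx - 1) / fs
  dirs <- d[idx - 1L]

  onsets <- numeric(0)
  offsets <- numeric(0)
  state <- if (length(x) > 0 && x[1] == 1L) 1L else 0L
  last_accept <- -Inf
  for (k in seq_along(idx)) {
    if (times[k] - last_accept < refractory) next
    if (dirs[k] == 1L && state == 0L) {
      onsets <- c(onsets, times[k])
      state <- 1L
      last_accept <- times[k]
    } else if (dirs[k] == -1L && state == 1L) {
      if (length(onsets) > length(offsets)) offsets <- c(offsets, times[k])
      state <- 0L
      last_accept <- times[k]
    }
  }
  if (length(onsets) == 0) {
    return(pulse_seq(numeric(0), offsets = numeric(0), source = source))
  }
  if (length(offsets) < length(onsets)) {
    offsets <- c(offsets, rep(NA_real_, length(onsets) - length(offsets)))
  }
  pulse_seq(onsets, offsets = offsets, source = source)
}

#' Parse a photodiode trace into pulse times
#'
#' Convenience composition of [binarize()] and [detect_transitions()]:
#' threshold, binarize, discrete-difference, transition localization.
#'
#' @inheritParams binarize
#' @inheritParams detect_transitions
#' @return A [pulse_seq()] tagged `"photodiode"`.
#' @export
parse_photodiode <- function(trace, threshold = "auto", refractory = NULL) {
  refractory <- refractory %||% (2 / trace_fs(trace))
  detect_transitions(binarize(trace, threshold = threshold),
                     refractory = refractory)
}

#' Extract key-press onsets from an audio trace
#'
#' Rectifies the audio, smooths it with a trailing moving-average envelope,
#' thresholds the envelope and runs the same transition localization as the
#' photodiode pipeline. The envelope window is deliberately short (2 ms) so
#' that the detected onset lags the physical burst start by at most about a
#' millisecond; the refractory period (default 50 ms) merges multi-peak
#' bursts into a single press.
#'
#' @param trace An [analog_trace()] of microphone audio.
#' @param envelope_window Moving-average window in seconds.
#' @param threshold Envelope threshold, or `"auto"`. Because presses occupy
#'   a tiny fraction of the recording, percentile midpoints would sit in
#'   the noise floor; the automatic envelope threshold is therefore the
#'   midpoint between the 1st percentile and the maximum of the envelope.
#' @param refractory Minimum separation between accepted presses, seconds.
#' @return A [pulse_seq()] tagged `"microphone"` (onsets only).
#' @export
extract_audio_onsets <- function(trace, envelope_window = 0.002,
                                 threshold = "auto", refractory = 0.05) {
  fs <- trace_fs(trace)
  w <- max(1L, round(envelope_window * fs))
  env <- as.numeric(stats::filter(abs(trace$value), rep(1 / w, w),
                                  sides = 1))
  env[seq_len(min(w - 1L, length(env)))] <- env[w]
  env_trace <- analog_trace(env, fs = fs, start_time = trace_start(trace),
                            source = "microphone")
  if (identical(threshold, "auto")) {
    lo <- stats::quantile(env, 0.01, names = FALSE)
    hi <- max(env)
    if (hi <= lo || isTRUE(all.equal(lo, hi))) {
      abort("cannot separate on/off states: envelope is constant.")
    }
    threshold <- (lo + hi) / 2
  }
  pulses <- detect_transitions(binarize(env_trace, threshold = threshold),
                               refractory = 0)
  # the refractory applies to press onsets: a multi-peak burst is one press
  onsets <- numeric(0)
  last <- -Inf
  for (t in pulses$onset_s) {
    if (t - last >= refractory) {
      onsets <- c(onsets, t)
      last <- t
    }
  }
  pulse_seq(onsets, source = "microphone")
}

#' Pair detected pulses with logged events
#'
#' Under the default flash scheme every event produces two pulses (one at
#' onset, one at offset), so 2n pulses must be detected for n logged events;
#' under `"onset_only"` the counts must match one to one. A count mismatch is
#' a hard error -- it indicates photodiode signal-quality problems that need
#' intervention, not silent repair -- and the error reports both counts plus
#' the first event at which the detected inter-pulse intervals diverge from
#' the log's expectation.
#'
#' @param pulses A [pulse_seq()] of detected pulses (flash starts).
#' @param log An event-log tibble (controlled rows are used).
#' @param scheme `"onset_and_offset"` or `"onset_only"`.
#' @param tol Interval-divergence tolerance in seconds used only for the
#'   diagnostic localization.
#' @return A tibble with `event_index`, `physical_onset_s` and, under the
#'   paired scheme, `physical_offset_s`.
#' @export
pair_pulses_to_events <- function(pulses, log,
                                  scheme = c("onset_and_offset", "onset_only"),
                                  tol = 0.01) {
  scheme <- match.arg(scheme)
  stim <- log[log$event_class %in% c(NA, "controlled"), , drop = FALSE]
  n_log <- nrow(stim)
  n_pulse <- nrow(pulses)
  per_event <- if (scheme == "onset_and_offset") 2L else 1L
  expected_pulses <- per_event * n_log

  if (n_pulse != expected_pulses) {
    # expected pulse times on the log clock, for the divergence diagnostic
    exp_times <- if (per_event == 2L) {
      as.vector(rbind(stim$onset_s, stim$onset_s + stim$planned_duration_s))
    } else {
      stim$onset_s
    }
    k <- first_interval_divergence(pulses$onset_s, exp_times, tol)
    at <- if (is.na(k)) min(n_pulse, expected_pulses) + 1L else k + 1L
    abort(sprintf(
      paste0("pulse/event count mismatch: %d logged events expect %d pulses",
             " but %d were detected; first interval divergence near event %d."),
      n_log, expected_pulses, n_pulse, ceiling(at / per_event)
    ))
  }
  if (per_event == 2L) {
    tibble(
      event_index = stim$event_index,
      physical_onset_s = pulses$onset_s[seq(1, n_pulse, by = 2)],
      physical_offset_s = pulses$onset_s[seq(2, n_pulse, by = 2)]
    )
  } else {
    tibble(event_index = stim$event_index,
           physical_onset_s = pulses$onset_s)
  }
}

# First index k (in interval space) where the two interval sequences differ
# by more than tol; NA when the overlapping part agrees.
first_interval_divergence <- function(obs_times, exp_times, tol) {
  d_obs <- diff(obs_times)
  d_exp <- diff(exp_times)
  m <- min(length(d_obs), length(d_exp))
  if (m < 1) return(NA_integer_)
  bad <- which(abs(d_obs[seq_len(m)] - d_exp[seq_len(m)]) > tol)
  if (length(bad) == 0) NA_integer_ else bad[1]
}
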