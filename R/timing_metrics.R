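#' Per-event timing-discrepancy series
#'
#' All timing metrics in the package return a `delta_series`: a tibble with
#' one row per event (or per inter-event interval) holding the discrepancy in
#' seconds, tagged with the kind of comparison it came from. Sign
#' conventions are kept literal and are worth stating prominently because
#' they are the most likely place for an implementation bug:
#'
#' * interval-based kinds (`log_timing`, `trigger_jitter`,
#'   `response_timing`): value i = (physical interval i) - (other stream's
#'   interval i), so n values arise from n+1 events;
#' * `trigger_delay`: value i = physical timestamp i - trigger timestamp i;
#' * `duration_vs_plan`: value i = observed duration i - planned duration i.
#'
#' @param values Discrepancies in seconds.
#' @param kind One of `"log_timing"`, `"duration_vs_plan"`,
#'   `"trigger_jitter"`, `"trigger_delay"`, `"response_timing"`.
#' @return A tibble of class `delta_series` with columns `i`, `delta_s`.
#' @export
delta_series <- function(values,
                         kind = c("log_timing", "duration_vs_plan",
                                  "trigger_jitter", "trigger_delay",
                                  "response_timing")) {
  kind <- match.arg(kind)
  out <- tibble(i = seq_along(values), delta_s = as.numeric(values))
  structure(out, kind = kind, class = c("delta_series", class(out)))
}

#' @export
print.delta_series <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<delta_series:%s> n=%d mean=%s sd=%s max|d|=%s\n",
    attr(x, "kind"), g$n, format_ms(g$mean_s), format_ms(g$sd_s),
    format_ms(g$max_abs_s)
  ))
  invisible(x)
}

#' @export
tidy.delta_series <- function(x, ...) {
  tibble(i = x$i, delta_s = x$delta_s, kind = attr(x, "kind"))
}

#' Summarize a delta series
#'
#' Mean, sample standard deviation (n-1 denominator; reported as 0 with a
#' `low_n` flag when only one value is available) and maximum absolute
#' deviation, in seconds. This is the summary the standardized report
#' prints, converted there to milliseconds.
#'
#' @param x A [delta_series()].
#' @param ... Unused.
#' @return A one-row tibble: `kind`, `n`, `mean_s`, `sd_s`, `max_abs_s`,
#'   `low_n`.
#' @export
glance.delta_series <- function(x, ...) {
  n <- nrow(x)
  if (n == 0) abort("cannot summarize an empty delta series.")
  tibble(
    kind = attr(x, "kind"),
    n = n,
    mean_s = mean(x$delta_s),
    sd_s = sd_or_zero(x$delta_s),
    max_abs_s = max(abs(x$delta_s)),
    low_n = n < 2
  )
}

#' @rdname glance.delta_series
#' @param sd_warn_s Calibration threshold: a series whose SD exceeds this
#'   (default 5 ms) is flagged `"warn"`, otherwise `"pass"`. A
#'   well-calibrated setup is expected to show a mean near zero with an SD
#'   on the order of milliseconds.
#' @export
delta_summary <- function(x, sd_warn_s = 0.005) {
  g <- glance(x)
  g$status <- if (g$sd_s > sd_warn_s) "warn" else "pass"
  g
}

#' Intervals between successive event times
#'
#' The discrete difference of a timestamp sequence: `out[i] = t[i+1] - t[i]`.
#'
#' @param times A [pulse_seq()] or numeric vector of timestamps in seconds.
#' @return Numeric vector of n-1 intervals for n timestamps.
#' @export
#' @examples
#' interval_series(c(0, 1, 2.5))
interval_series <- function(times) {
  if (inherits(times, "pulse_seq")) times <- times$onset_s
  if (is.data.frame(times)) times <- times$onset_s
  if (length(times) < 2) abort("need at least 2 timestamps to form intervals.")
  diff(times)
}

# Shared core of the interval-difference metrics (Delta_i and Delta_r style):
# value i = (physical interval i) - (reference interval i).
interval_difference <- function(physical, reference, kind) {
  n_p <- length(physical)
  n_r <- length(reference)
  if (n_p != n_r) {
    abort(sprintf(
      "event count mismatch: %d physical vs %d reference timestamps.",
      n_p, n_r
    ))
  }
  delta_series(interval_series(physical) - interval_series(reference),
               kind = kind)
}

#' Log-file timestamping inaccuracy
#'
#' Compares intervals between successive physical (photodiode) event onsets
#' with intervals between the corresponding logged onsets. Working on
#' intervals makes the metric exactly invariant to any constant clock offset
#' between the two streams, so it isolates per-event jitter; a constant
#' display delay cancels.
#'
#' @param photo A [pulse_seq()] (or numeric onsets) of physical event
#'   onsets, e.g. column `physical_onset_s` of [pair_pulses_to_events()].
#' @param log Event-log tibble (controlled rows are used) or numeric logged
#'   onsets.
#' @return A [delta_series()] of kind `"log_timing"` with n-1 values for n
#'   events.
#' @export
#' @examples
#' logging_inaccuracy(c(0.5, 1.516, 2.5), c(0, 1, 2))
logging_inaccuracy <- function(photo, log) {
  interval_difference(onsets_of(photo), logged_onsets(log), "log_timing")
}

#' Observed versus planned event durations
#'
#' Duration of each event as seen by the photodiode (offset minus onset)
#' minus its planned duration.
#'
#' @param photo A [pulse_seq()] with onsets and offsets, or the paired table
#'   from [pair_pulses_to_events()] (columns `physical_onset_s`,
#'   `physical_offset_s`).
#' @param log Event-log tibble carrying `planned_duration_s` for every
#'   controlled event.
#' @return A [delta_series()] of kind `"duration_vs_plan"`.
#' @export
duration_deviation <- function(photo, log) {
  if (is.data.frame(photo) && "physical_offset_s" %in% names(photo)) {
    onsets <- photo$physical_onset_s
    offsets <- photo$physical_offset_s
  } else if (inherits(photo, "pulse_seq") && "offset_s" %in% names(photo)) {
    onsets <- photo$onset_s
    offsets <- photo$offset_s
  } else {
    abort(paste0(
      "offsets are missing: record the photodiode with the",
      " 'onset_and_offset' flash scheme to measure durations."
    ))
  }
  if (any(is.na(offsets))) {
    abort("offsets contain NA; cannot compute observed durations.")
  }
  stim <- if (is.data.frame(log) && "event_class" %in% names(log)) {
    log[log$event_class == "controlled", , drop = FALSE]
  } else {
    log
  }
  planned <- stim$planned_duration_s
  if (is.null(planned) || any(is.na(planned))) {
    abort("`planned_duration_s` must be present for every event.")
  }
  if (length(onsets) != length(planned)) {
    abort(sprintf(
      "event count mismatch: %d observed vs %d planned durations.",
      length(onsets), length(planned)
    ))
  }
  delta_series((offsets - onsets) - planned, kind = "duration_vs_plan")
}

#' Peripheral trigger jitter
#'
#' Interval-difference between the physical event stream and the trigger
#' stream: value i = (photo interval i) - (trigger interval i). Being
#' interval-based it is invariant to any constant offset between the two
#' clocks, so it estimates jitter only -- by design it cannot see a constant
#' delay (use [trigger_delay()] for that).
#'
#' @param photo Physical event onsets ([pulse_seq()] or numeric).
#' @param trig Trigger stream (tibble with `timestamp_s`, a [pulse_seq()],
#'   or numeric timestamps).
#' @return A [delta_series()] of kind `"trigger_jitter"`.
#' @export
trigger_jitter <- function(photo, trig) {
  interval_difference(onsets_of(photo), trigger_times(trig),
                      "trigger_jitter")
}

#' Peripheral trigger delay
#'
#' Direct timestamp difference, value i = photo_i - trig_i. Only meaningful
#' when the photodiode signal and the triggers were recorded on the same
#' clock (the caller asserts this; the report flags the assumption). A
#' positive mean means the physical event occurs after its trigger
#' timestamp. The attribute `drift_s_per_s` carries the slope of the
#' differences against time, a diagnostic for clock drift between the two
#' streams; it is reported, never corrected for.
#'
#' @inheritParams trigger_jitter
#' @return A [delta_series()] of kind `"trigger_delay"` with n values for n
#'   events.
#' @export
#' @examples
#' trigger_delay(1.032, 1.000)$delta_s
trigger_delay <- function(photo, trig) {
  p <- onsets_of(photo)
  tr <- trigger_times(trig)
  if (length(p) != length(tr)) {
    abort(sprintf(
      "event count mismatch: %d physical vs %d trigger timestamps.",
      length(p), length(tr)
    ))
  }
  out <- delta_series(p - tr, kind = "trigger_delay")
  drift <- if (length(p) >= 3 && stats::var(p) > 0) {
    unname(stats::coef(stats::lm(I(p - tr) ~ p))[2])
  } else {
    NA_real_
  }
  attr(out, "drift_s_per_s") <- drift
  out
}

#' Response timestamping inaccuracy
#'
#' The uncontrolled-event analogue of [logging_inaccuracy()]: intervals
#' between physical press onsets (from the microphone) minus intervals
#' between the logged response timestamps.
#'
#' @param audio Press onsets ([pulse_seq()] or numeric), e.g. from
#'   [extract_audio_onsets()].
#' @param log Event-log tibble; only rows with
#'   `event_class == "uncontrolled"` are used. Numeric timestamps are also
#'   accepted.
#' @return A [delta_series()] of kind `"response_timing"`.
#' @export
response_inaccuracy <- function(audio, log) {
  logged <- if (is.data.frame(log) && "event_class" %in% names(log)) {
    log$onset_s[log$event_class == "uncontrolled"]
  } else {
    logged_onsets(log)
  }
  interval_difference(onsets_of(audio), logged, "response_timing")
}

onsets_of <- function(x) {
  if (inherits(x, "pulse_seq")) return(x$onset_s)
  if (is.data.frame(x)) {
    for (col in c("physical_onset_s", "onset_s")) {
      if (col %in% names(x)) return(x[[col]])
    }
    abort("no onset column found.")
  }
  as.numeric(x)
}

logged_onsets <- function(log) {
  if (is.data.frame(log)) {
    if ("event_class" %in% names(log)) {
      return(log$onset_s[log$event_class == "controlled"])
    }
    return(log$onset_s)
  }
  as.numeric(log)
}

trigger_times <- function(trig) {
  if (is.data.frame(trig) && "timestamp_s" %in% names(trig)) {
    return(trig$timestamp_s)
  }
  onsets_of(trig)
}
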