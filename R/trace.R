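#' Uniformly sampled analog trace
#'
#' Container for a physical signal (photodiode luminance, microphone audio)
#' sampled at a constant rate. Stored as a tibble with columns `time_s` and
#' `value`; the sampling rate and start time travel along as attributes so
#' the object can be handed straight to the parsing functions.
#'
#' @param samples Numeric vector of sample values (arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param start_time Time of the first sample in seconds.
#' @param source Optional tag describing the signal source
#'   (`"photodiode"`, `"microphone"`, ...).
#' @return A tibble of class `analog_trace` with columns `time_s`, `value`.
#' @export
#' @examples
#' tr <- analog_trace(c(0, 0, 5, 5, 0), fs = 1000)
#' trace_fs(tr)
analog_trace <- function(samples, fs, start_time = 0, source = NULL) {
  assert_positive(fs, "fs")
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    abort("`samples` must be finite numeric values.")
  }
  out <- tibble(
    time_s = start_time + (seq_along(samples) - 1) / fs,
    value = as.numeric(samples)
  )
  structure(out,
    fs = fs, start_time = start_time, source = source,
    class = c("analog_trace", class(out))
  )
}

#' @rdname analog_trace
#' @param trace An `analog_trace`.
#' @export
trace_fs <- function(trace) attr(trace, "fs")

#' @rdname analog_trace
#' @export
trace_start <- function(trace) attr(trace, "start_time")

#' @export
print.analog_trace <- function(x, ...) {
  cat(sprintf(
    "<analog_trace> %d samples @ %g Hz, start %.6g s%s\n",
    nrow(x), trace_fs(x), trace_start(x),
    if (is.null(attr(x, "source"))) "" else paste0(" [", attr(x, "source"), "]")
  ))
  NextMethod()
}

#' Sequence of physical event times
#'
#' Ordered pulse onsets (and optionally offsets) extracted from a physical
#' signal or constructed as fixture ground truth. Onsets must be strictly
#' increasing; when offsets are present each offset must follow its onset.
#'
#' @param onsets Onset times in seconds, strictly increasing.
#' @param offsets Optional offset times in seconds (same length as `onsets`,
#'   `NA` allowed for a trailing unterminated pulse).
#' @param source Tag: `"photodiode"`, `"microphone"`, `"trigger"` or `"log"`.
#' @return A tibble of class `pulse_seq` with columns `pulse`, `onset_s`
#'   and, when offsets are given, `offset_s`.
#' @export
#' @examples
#' pulse_seq(c(0.5, 1.5), offsets = c(0.6, 1.6), source = "photodiode")
pulse_seq <- function(onsets, offsets = NULL, source = "photodiode") {
  if (length(onsets) > 1 && any(diff(onsets) <= 0)) {
    abort("pulse onsets must be strictly increasing.")
  }
  out <- tibble(pulse = seq_along(onsets), onset_s = as.numeric(onsets))
  if (!is.null(offsets)) {
    if (length(offsets) != length(onsets)) {
      abort("`offsets` must have the same length as `onsets`.")
    }
    bad <- which(!is.na(offsets) & offsets <= onsets)
    if (length(bad) > 0) {
      abort(sprintf("offset %d does not follow its onset.", bad[1]))
    }
    out$offset_s <- as.numeric(offsets)
  }
  structure(out, source = source, class = c("pulse_seq", class(out)))
}

#' @export
print.pulse_seq <- function(x, ...) {
  cat(sprintf(
    "<pulse_seq> %d pulses [%s]\n", nrow(x),
    attr(x, "source") %||% "unknown"
  ))
  NextMethod()
}

# Strip the pulse_seq class after dplyr verbs would otherwise drop attributes.
as_pulse_seq <- function(df, source = "photodiode") {
  pulse_seq(df$onset_s, offsets = df[["offset_s"]], source = source)
}
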