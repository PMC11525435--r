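# Readers and writers for the plain-text interchange formats: event logs and
# trigger streams as CSV, analog traces as two-column CSV or mono WAV.

#' Read and write event logs
#'
#' CSV with header, one row per event:
#' `event_index, onset_s, planned_onset_s, planned_duration_s,
#' <factor columns>, event_class, response_key`.
#'
#' @param path File path.
#' @param log Event-log tibble (as produced by [generate_experiment()]).
#' @return `read_event_log()` returns a tibble with the factor columns
#'   recorded in the `"factors"` attribute.
#' @export
read_event_log <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                           na.strings = c("", "NA")))
  reserved <- c("event_index", "onset_s", "planned_onset_s",
                "planned_duration_s", "event_class", "response_key",
                "block")
  attr(df, "factors") <- setdiff(names(df), reserved)
  df
}

#' @rdname read_event_log
#' @export
write_event_log <- function(log, path) {
  write.csv(as.data.frame(log), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write trigger streams
#'
#' CSV with columns `timestamp_s, code`.
#'
#' @param path File path.
#' @param triggers Tibble with `timestamp_s`, `code`.
#' @export
read_trigger_stream <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("timestamp_s", "code") %in% names(df))) {
    abort("trigger CSV needs columns `timestamp_s` and `code`.")
  }
  df
}

#' @rdname read_trigger_stream
#' @export
write_trigger_stream <- function(triggers, path) {
  write.csv(as.data.frame(triggers), path, row.names = FALSE)
  invisible(path)
}

#' Read and write analog traces as CSV
#'
#' Two columns `time_s, value`; the sampling rate is recovered from the
#' time stamps (or supplied explicitly).
#'
#' @param path File path.
#' @param trace An [analog_trace()].
#' @param fs Sampling rate override in Hz.
#' @export
read_trace_csv <- function(path, fs = NULL) {
  df <- read.csv(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    abort("trace CSV needs columns `time_s` and `value`.")
  }
  fs <- fs %||% (1 / stats::median(diff(df$time_s)))
  analog_trace(df$value, fs = fs, start_time = df$time_s[1])
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(data.frame(time_s = trace$time_s, value = trace$value), path,
            row.names = FALSE)
  invisible(path)
}

#' Read and write mono WAV files
#'
#' Minimal RIFF/WAVE codec for the two encodings used in practice for
#' test recordings: 16-bit PCM and 32-bit IEEE float, single channel. No
#' audio package ships with the supported R stack, and the format is simple
#' enough to read directly.
#'
#' @param path File path.
#' @param trace An [analog_trace()]; values outside [-1, 1] are clipped for
#'   PCM.
#' @param encoding `"pcm16"` or `"float32"`.
#' @return `read_wav()` returns an [analog_trace()] with `fs` taken from
#'   the header; PCM samples are rescaled to [-1, 1].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("not a RIFF file.")
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("not a WAVE file.")

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = readBin(con, "integer", 1, size = 2, endian = "little"),
        channels = readBin(con, "integer", 1, size = 2, endian = "little"),
        fs = readBin(con, "integer", 1, size = 4, endian = "little")
      )
      readBin(con, "integer", 1, size = 4, endian = "little") # byte rate
      readBin(con, "integer", 1, size = 2, endian = "little") # block align
      fmt$bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) abort("malformed WAV: data before fmt chunk.")
      if (fmt$channels != 1) abort("only mono WAV is supported.")
      if (fmt$format == 1 && fmt$bits == 16) {
        samples <- readBin(con, "integer", size / 2, size = 2,
                           endian = "little") / 32767
      } else if (fmt$format == 3 && fmt$bits == 32) {
        samples <- readBin(con, "double", size / 4, size = 4,
                           endian = "little")
      } else {
        abort("only 16-bit PCM and 32-bit float WAV are supported.")
      }
    } else {
      readBin(con, "raw", size)
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) abort("no data chunk found.")
  analog_trace(samples, fs = fmt$fs, source = "microphone")
}

#' @rdname read_wav
#' @export
write_wav <- function(trace, path, encoding = c("float32", "pcm16")) {
  encoding <- match.arg(encoding)
  fs <- as.integer(round(trace_fs(trace)))
  v <- trace$value
  bytes_per <- if (encoding == "float32") 4L else 2L
  data_size <- length(v) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (encoding == "float32") 3L else 1L, con, size = 2,
           endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * as.integer(bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(8L * as.integer(bytes_per), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (encoding == "float32") {
    writeBin(as.numeric(v), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(-1, pmin(1, v)) * 32767)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an analog trace from CSV or WAV
#'
#' Dispatches on the file extension.
#'
#' @param path File path ending in `.csv` or `.wav`.
#' @param fs Sampling rate override (CSV only).
#' @return An [analog_trace()].
#' @export
read_analog <- function(path, fs = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    wav = read_wav(path),
    csv = read_trace_csv(path, fs = fs),
    abort(sprintf("unsupported trace format: .%s", ext))
  )
}
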