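#' Experimental plan
#'
#' Declarative description of an event-based experiment: how many stimulus
#' events, which condition factors (full cross, balanced), the planned
#' duration of each event, the gap between events, and optionally an ordered
#' response plan for participant key presses.
#'
#' @param n_events Number of stimulus (controlled) events.
#' @param factors Named list of factor levels, e.g.
#'   `list(category = c("face", "object"), location = c("left", "right"))`.
#'   Events are assigned a balanced full cross of the levels.
#' @param planned_durations Planned stimulus duration(s) in seconds; recycled
#'   to `n_events`.
#' @param inter_event_interval Gap in seconds between the offset of one event
#'   and the onset of the next; recycled to `n_events`.
#' @param response_plan Optional tibble/data frame with columns `key` and
#'   `presses` (presses per responded event, default 1); recycled across
#'   events. Each planned press becomes an uncontrolled log event.
#' @param t0 Onset of the first event in seconds.
#' @return An object of class `experiment_plan`.
#' @export
#' @examples
#' experiment_plan(12, factors = list(category = c("face", "object")))
experiment_plan <- function(n_events,
                            factors = list(category = c("face", "object")),
                            planned_durations = 0.5,
                            inter_event_interval = 1.0,
                            response_plan = NULL,
                            t0 = 1.0) {
  stopifnot(is.numeric(n_events), n_events >= 1)
  n_events <- as.integer(n_events)
  assert_positive(planned_durations, "planned_durations")
  assert_positive(inter_event_interval, "inter_event_interval")
  if (!is.list(factors) || is.null(names(factors)) || any(names(factors) == "")) {
    abort("`factors` must be a named list of level vectors.")
  }
  if (!is.null(response_plan)) {
    response_plan <- as_tibble(response_plan)
    if (!"key" %in% names(response_plan)) {
      abort("`response_plan` needs a `key` column.")
    }
    if (!"presses" %in% names(response_plan)) response_plan$presses <- 1L
    response_plan$presses <- as.integer(response_plan$presses)
    if (any(response_plan$presses < 0)) abort("`presses` must be >= 0.")
  }
  durations <- rep_len(as.numeric(planned_durations), n_events)
  gaps <- rep_len(as.numeric(inter_event_interval), n_events)
  structure(
    list(
      n_events = n_events,
      factors = factors,
      planned_durations = durations,
      inter_event_interval = gaps,
      response_plan = response_plan,
      t0 = t0
    ),
    class = "experiment_plan"
  )
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf(
    "<experiment_plan> %d events, factors: %s\n", x$n_events,
    paste(names(x$factors), collapse = " x ")
  ))
  cat(sprintf(
    "  total planned span: %.3f s\n",
    sum(x$planned_durations) + sum(x$inter_event_interval)
  ))
  invisible(x)
}

#' Corruption specification for synthetic fixtures
#'
#' Describes the defects injected into a synthetic experiment log so that
#' every downstream metric can be validated by parameter recovery. A delay is
#' a constant shift of the logged clock against the physical clock; jitter is
#' per-event timing noise (Gaussian via `jitter_sd`, or fixed-magnitude
#' random-sign on a random subset via `jitter_magnitude` +
#' `jitter_proportion`).
#'
#' @param clock_delay Constant shift (seconds) added to logged onsets.
#' @param jitter_sd SD (seconds) of zero-mean Gaussian per-event noise added
#'   to logged onsets.
#' @param jitter_magnitude Fixed magnitude (seconds) of +/- timing error.
#' @param jitter_proportion Fraction of events receiving the fixed-magnitude
#'   error.
#' @param drop_events Number of events silently missing from the log.
#' @param label_errors Number of events whose condition label is mislogged.
#' @param seed Default RNG seed used by [generate_experiment()] when its own
#'   `seed` argument is `NULL`.
#' @return An object of class `corruption_spec`.
#' @export
#' @examples
#' corruption_spec(clock_delay = 0.032, jitter_sd = 0.005)
corruption_spec <- function(clock_delay = 0,
                            jitter_sd = 0,
                            jitter_magnitude = 0,
                            jitter_proportion = 0,
                            drop_events = 0,
                            label_errors = 0,
                            seed = NULL) {
  if (jitter_sd < 0 || jitter_magnitude < 0) {
    abort("jitter magnitudes must be >= 0.")
  }
  assert_proportion(jitter_proportion, "jitter_proportion")
  stopifnot(drop_events >= 0, label_errors >= 0)
  structure(
    list(
      clock_delay = clock_delay,
      jitter_sd = jitter_sd,
      jitter_magnitude = jitter_magnitude,
      jitter_proportion = jitter_proportion,
      drop_events = as.integer(drop_events),
      label_errors = as.integer(label_errors),
      seed = seed
    ),
    class = "corruption_spec"
  )
}

#' @export
print.corruption_spec <- function(x, ...) {
  cat("<corruption_spec>\n")
  cat(sprintf("  clock_delay: %s\n", format_ms(x$clock_delay)))
  cat(sprintf("  jitter_sd:   %s\n", format_ms(x$jitter_sd)))
  if (x$jitter_magnitude > 0) {
    cat(sprintf(
      "  fixed jitter: +/-%s on %.0f%% of events\n",
      format_ms(x$jitter_magnitude), 100 * x$jitter_proportion
    ))
  }
  cat(sprintf(
    "  drop_events: %d, label_errors: %d\n",
    x$drop_events, x$label_errors
  ))
  invisible(x)
}

#' Read a plan or corruption specification from YAML
#'
#' The YAML fields mirror the constructor arguments one to one.
#'
#' @param path Path to a YAML file.
#' @return An `experiment_plan` or `corruption_spec`.
#' @export
read_plan <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$response_plan)) {
    y$response_plan <- as_tibble(as.data.frame(y$response_plan))
  }
  do.call(experiment_plan, y)
}

#' @rdname read_plan
#' @export
read_corruption <- function(path) {
  do.call(corruption_spec, yaml::read_yaml(path))
}
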