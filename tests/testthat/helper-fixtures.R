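# Shared fixture builders. Everything is generated in code at test time;
# seeds are fixed so expectations are deterministic.

std_plan <- function(n = 12, with_responses = TRUE, ...) {
  experiment_plan(
    n,
    factors = list(category = c("face", "object"),
                   location = c("left", "right")),
    planned_durations = 0.5,
    inter_event_interval = 1.0,
    response_plan = if (with_responses) {
      tibble::tibble(key = c("f", "j"), presses = 1L)
    } else {
      NULL
    },
    ...
  )
}

clean_fixture <- function(n = 12, seed = 7, with_responses = TRUE) {
  generate_experiment(std_plan(n, with_responses), corruption_spec(),
                      seed = seed)
}

# Ground-truth annotation table for a fixture: the log's controlled rows
# with any injected label corruption reverted.
fixture_truth_table <- function(fx) {
  truth <- fx$log[fx$log$event_class == "controlled",
                  c("event_index", attr(fx$log, "factors"))]
  inj <- fx$injected$label_error_rows
  for (k in seq_len(nrow(inj))) {
    i <- which(truth$event_index == inj$event_index[k])
    truth[[inj$field[k]]][i] <- inj$original[k]
  }
  truth
}
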