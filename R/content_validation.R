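#' Compare logged event content against ground truth
#'
#' Field-by-field equality check of the log against an annotation table (a
#' manual transcript of what was actually on screen, or fixture ground
#' truth) keyed by `event_index`. The truth table may cover a subset of
#' rows; coverage is reported per realized condition (full cross of the
#' declared factor columns), and conditions with no annotated event are
#' listed as coverage shortfalls since each condition should be checked at
#' least once. A functioning setup must show zero mismatches.
#'
#' @param log Event-log tibble.
#' @param truth Annotation tibble with `event_index` plus any content
#'   columns to check (same names as in the log). Timing columns
#'   (`onset_s`) are ignored: this test is about content.
#' @param factors Character vector of condition-defining columns; defaults
#'   to the log's `factors` attribute, else to the factor-like columns the
#'   two tables share.
#' @return A list of class `content_report`: `summary` (one row),
#'   `coverage` (events tested per condition), `mismatches` (row, field,
#'   logged vs expected), `untested_conditions`.
#' @export
compare_event_content <- function(log, truth, factors = NULL) {
  truth <- as_tibble(truth)
  if (!"event_index" %in% names(truth)) {
    abort("`truth` must carry `event_index` to key into the log.")
  }
  unknown <- setdiff(truth$event_index, log$event_index)
  if (length(unknown) > 0) {
    abort(sprintf(
      "truth refers to unknown event_index: %s",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  fields <- setdiff(
    intersect(names(truth), names(log)),
    c("event_index", "onset_s", "planned_onset_s")
  )
  if (length(fields) == 0) abort("no shared content fields to compare.")
  factors <- factors %||% attr(log, "factors") %||%
    setdiff(fields, c("planned_duration_s", "event_class", "response_key"))

  logged <- log[match(truth$event_index, log$event_index), , drop = FALSE]
  mismatches <- purrr::map(fields, function(f) {
    bad <- which(!values_match(logged[[f]], truth[[f]]))
    if (length(bad) == 0) return(NULL)
    tibble(
      event_index = truth$event_index[bad], field = f,
      logged = as.character(logged[[f]][bad]),
      expected = as.character(truth[[f]][bad])
    )
  })
  mismatches <- dplyr::bind_rows(mismatches)
  if (nrow(mismatches) == 0) {
    mismatches <- tibble(
      event_index = integer(), field = character(),
      logged = character(), expected = character()
    )
  }

  # coverage over conditions realized in the log (controlled rows)
  stim <- if ("event_class" %in% names(log)) {
    log[log$event_class == "controlled", , drop = FALSE]
  } else {
    log
  }
  cov_factors <- intersect(factors, names(stim))
  if (length(cov_factors) > 0) {
    realized <- dplyr::distinct(stim[, cov_factors, drop = FALSE])
    tested <- stim[stim$event_index %in% truth$event_index, , drop = FALSE]
    coverage <- dplyr::count(tested, dplyr::across(dplyr::all_of(cov_factors)),
                             name = "n_tested")
    coverage <- dplyr::left_join(realized, coverage, by = cov_factors)
    coverage$n_tested[is.na(coverage$n_tested)] <- 0L
    untested <- coverage[coverage$n_tested == 0L, cov_factors, drop = FALSE]
  } else {
    coverage <- tibble(n_tested = nrow(truth))
    untested <- tibble()
  }

  structure(
    list(
      summary = tibble(
        n_conditions_tested = sum(coverage$n_tested > 0),
        n_conditions_realized = nrow(coverage),
        n_events_tested = nrow(truth),
        n_mismatches = nrow(mismatches)
      ),
      coverage = coverage,
      mismatches = mismatches,
      untested_conditions = untested
    ),
    class = "content_report"
  )
}

# Element-wise equality with NA == NA a match and a float tolerance for
# numeric fields (values that round-tripped through CSV must still match).
values_match <- function(a, b) {
  both_na <- is.na(a) & is.na(b)
  if (is.numeric(a) && is.numeric(b)) {
    same <- abs(a - b) < 1e-9
  } else {
    same <- as.character(a) == as.character(b)
  }
  same[is.na(same)] <- FALSE
  same | both_na
}

#' @export
print.content_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<content_report> %d mismatches / %d events tested (%d/%d conditions covered)\n",
    s$n_mismatches, s$n_events_tested, s$n_conditions_tested,
    s$n_conditions_realized
  ))
  if (s$n_mismatches > 0) print(x$mismatches)
  invisible(x)
}

#' @export
tidy.content_report <- function(x, ...) x$mismatches

#' @export
glance.content_report <- function(x, ...) x$summary

#' Check logged responses against the response plan
#'
#' Positional comparison of the executed response sequence (the preplanned
#' "recipe" of key presses, including deliberate wrong keys, multiple
#' presses, and presses at unexpected moments) against the responses the
#' log recorded. Each planned press is one position. Missing presses are
#' mismatches, not errors: a planned repeat that was logged only once is
#' flagged `"missing repeat"`, extra logged responses are flagged
#' `"unexpected"`, and differing keys at a position are `"wrong key"`.
#'
#' @param log Event-log tibble; rows with `event_class == "uncontrolled"`
#'   in onset order are the logged responses. A bare character vector of
#'   logged keys is also accepted.
#' @param plan Tibble with columns `key` and optionally `presses`
#'   (default 1), in execution order; or a character vector of keys.
#' @return A list of class `response_report` with `summary` (number of
#'   response types, inaccurately logged count / total), `per_type` counts
#'   and a `mismatches` tibble (`position`, `expected`, `logged`, `type`).
#' @export
#' @examples
#' check_response_plan(c("a", "b", "b"), c("a", "a", "b"))
check_response_plan <- function(log, plan) {
  logged <- if (is.data.frame(log)) {
    rows <- log[log$event_class == "uncontrolled", , drop = FALSE]
    rows <- rows[order(rows$onset_s), , drop = FALSE]
    as.character(rows$response_key)
  } else {
    as.character(log)
  }
  if (is.data.frame(plan)) {
    if (!"presses" %in% names(plan)) plan$presses <- 1L
    expected <- rep(as.character(plan$key), times = plan$presses)
  } else {
    expected <- as.character(plan)
  }

  mm <- tibble(position = integer(), expected = character(),
               logged = character(), type = character())
  i <- 1L # position in expected
  j <- 1L # position in logged
  while (i <= length(expected) || j <= length(logged)) {
    if (i > length(expected)) {
      mm <- dplyr::bind_rows(mm, tibble(
        position = i, expected = NA_character_,
        logged = logged[j], type = "unexpected"
      ))
      j <- j + 1L
      next
    }
    if (j > length(logged)) {
      type <- if (i > 1 && identical(expected[i], expected[i - 1])) {
        "missing repeat"
      } else {
        "missing"
      }
      mm <- dplyr::bind_rows(mm, tibble(
        position = i, expected = expected[i],
        logged = NA_character_, type = type
      ))
      i <- i + 1L
      next
    }
    if (identical(expected[i], logged[j])) {
      i <- i + 1L
      j <- j + 1L
      next
    }
    # a planned repeat that the log skipped: only plausible when the log
    # has fewer remaining entries than the plan and the current logged key
    # matches the next planned press
    if (i > 1 && identical(expected[i], expected[i - 1]) &&
        i < length(expected) && identical(logged[j], expected[i + 1]) &&
        (length(expected) - i) > (length(logged) - j)) {
      mm <- dplyr::bind_rows(mm, tibble(
        position = i, expected = expected[i],
        logged = NA_character_, type = "missing repeat"
      ))
      i <- i + 1L
      next
    }
    mm <- dplyr::bind_rows(mm, tibble(
      position = i, expected = expected[i],
      logged = logged[j], type = "wrong key"
    ))
    i <- i + 1L
    j <- j + 1L
  }

  per_type <- dplyr::count(tibble(key = expected), .data$key,
                           name = "n_planned")
  structure(
    list(
      summary = tibble(
        n_response_types = length(unique(expected)),
        n_planned = length(expected),
        n_logged = length(logged),
        n_mismatches = nrow(mm)
      ),
      per_type = per_type,
      mismatches = mm
    ),
    class = "response_report"
  )
}

#' @export
print.response_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<response_report> %d mismatches / %d planned presses (%d types)\n",
    s$n_mismatches, s$n_planned, s$n_response_types
  ))
  if (s$n_mismatches > 0) print(x$mismatches)
  invisible(x)
}

#' @export
glance.response_report <- function(x, ...) x$summary

#' @export
tidy.response_report <- function(x, ...) x$mismatches

#' Declare experimental-design rules
#'
#' A declarative rule set the log can be audited against:
#' balanced-count expectations per condition combination, a cap on
#' consecutive same-level runs, and optional per-block counts.
#'
#' @param expected_counts Tibble of factor-level combinations with a column
#'   `n_expected` (nested combinations enumerated explicitly).
#' @param max_run Optional `list(factor = <column>, k = <max consecutive>)`.
#' @param blocks Optional tibble with columns `block` and `n_expected`
#'   (requires a `block` column in the log).
#' @return A `design_rules` object.
#' @export
design_rules <- function(expected_counts = NULL, max_run = NULL,
                         blocks = NULL) {
  if (!is.null(expected_counts)) {
    expected_counts <- as_tibble(expected_counts)
    if (!"n_expected" %in% names(expected_counts)) {
      abort("`expected_counts` needs an `n_expected` column.")
    }
  }
  if (!is.null(max_run) &&
      (is.null(max_run$factor) || is.null(max_run$k))) {
    abort("`max_run` must be list(factor = , k = ).")
  }
  structure(list(expected_counts = expected_counts, max_run = max_run,
                 blocks = blocks),
            class = "design_rules")
}

#' Validate a log against the design rules
#'
#' Counts, per rule, how many events comply out of the total tested, and
#' localizes every violation. Any deviation means the realized sequence
#' does not implement the intended design.
#'
#' @param log Event-log tibble (controlled rows are audited).
#' @param rules A [design_rules()] object.
#' @return A list of class `design_report`: `rules` (one row per rule with
#'   `n_compliant`, `n_total`, `pass`), `combo_counts` (observed vs expected
#'   per combination) and `violations`.
#' @export
validate_design_rules <- function(log, rules) {
  stopifnot(inherits(rules, "design_rules"))
  stim <- if ("event_class" %in% names(log)) {
    log[log$event_class == "controlled", , drop = FALSE]
  } else {
    log
  }
  stim <- stim[order(stim$onset_s), , drop = FALSE]
  n <- nrow(stim)
  rule_rows <- list()
  combo_counts <- NULL
  violations <- tibble(rule = character(), location = integer(),
                      detail = character())

  if (!is.null(rules$expected_counts)) {
    keys <- setdiff(names(rules$expected_counts), "n_expected")
    missing_cols <- setdiff(keys, names(stim))
    if (length(missing_cols) > 0) {
      abort(sprintf("rule references unknown factor(s): %s",
                    paste(missing_cols, collapse = ", ")))
    }
    obs <- dplyr::count(stim, dplyr::across(dplyr::all_of(keys)),
                        name = "n_observed")
    combo_counts <- dplyr::full_join(rules$expected_counts, obs, by = keys)
    combo_counts$n_observed[is.na(combo_counts$n_observed)] <- 0L
    combo_counts$n_expected[is.na(combo_counts$n_expected)] <- 0L
    n_compliant <- sum(pmin(combo_counts$n_observed,
                            combo_counts$n_expected))
    bad <- combo_counts[combo_counts$n_observed != combo_counts$n_expected, ,
                        drop = FALSE]
    if (nrow(bad) > 0) {
      detail <- apply(bad, 1, function(r) {
        paste0(paste(r[keys], collapse = "/"), ": observed ",
               r[["n_observed"]], ", expected ", r[["n_expected"]])
      })
      violations <- dplyr::bind_rows(violations, tibble(
        rule = "balanced_counts", location = NA_integer_, detail = detail
      ))
    }
    rule_rows$counts <- tibble(
      rule = "balanced_counts", n_compliant = n_compliant, n_total = n,
      pass = nrow(bad) == 0
    )
  }

  if (!is.null(rules$max_run)) {
    f <- rules$max_run$factor
    k <- rules$max_run$k
    if (!f %in% names(stim)) {
      abort(sprintf("rule references unknown factor: %s", f))
    }
    r <- rle(as.character(stim[[f]]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    long <- which(r$lengths > k)
    excess <- sum(pmax(r$lengths - k, 0))
    if (length(long) > 0) {
      violations <- dplyr::bind_rows(violations, tibble(
        rule = "max_run", location = starts[long],
        detail = sprintf("run of %d consecutive '%s' events starting at event %d (max %d)",
                         r$lengths[long], r$values[long], starts[long], k)
      ))
    }
    rule_rows$max_run <- tibble(
      rule = "max_run", n_compliant = n - excess, n_total = n,
      pass = length(long) == 0
    )
  }

  if (!is.null(rules$blocks)) {
    if (!"block" %in% names(stim)) {
      abort("rule references unknown factor: block")
    }
    obs_b <- dplyr::count(stim, .data$block, name = "n_observed")
    cmp <- dplyr::full_join(as_tibble(rules$blocks), obs_b, by = "block")
    cmp$n_observed[is.na(cmp$n_observed)] <- 0L
    bad_b <- cmp[cmp$n_observed != cmp$n_expected, , drop = FALSE]
    if (nrow(bad_b) > 0) {
      violations <- dplyr::bind_rows(violations, tibble(
        rule = "block_counts", location = NA_integer_,
        detail = sprintf("block %s: observed %d, expected %d",
                         as.character(bad_b$block), bad_b$n_observed,
                         bad_b$n_expected)
      ))
    }
    rule_rows$blocks <- tibble(
      rule = "block_counts",
      n_compliant = sum(pmin(cmp$n_observed, cmp$n_expected)),
      n_total = n, pass = nrow(bad_b) == 0
    )
  }

  if (length(rule_rows) == 0) abort("no rules declared.")
  structure(
    list(
      rules = dplyr::bind_rows(rule_rows),
      combo_counts = combo_counts,
      violations = violations
    ),
    class = "design_report"
  )
}

#' @export
print.design_report <- function(x, ...) {
  cat("<design_report>\n")
  print(x$rules)
  if (nrow(x$violations) > 0) print(x$violations)
  invisible(x)
}

#' @export
glance.design_report <- function(x, ...) {
  tibble(
    n_rules = nrow(x$rules),
    n_rules_passed = sum(x$rules$pass),
    n_violations = nrow(x$violations),
    pass = all(x$rules$pass)
  )
}

#' @export
tidy.design_report <- function(x, ...) x$rules
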