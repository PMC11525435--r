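#' Assemble the standardized QA report
#'
#' Collects the outputs of the individual tests into one standardized
#' report mirroring the recommended reporting structure: visual geometry,
#' logged event content, logged responses, event timing, design compliance
#' and peripheral triggers. Every section that was not computed is
#' explicitly marked `"not performed"` rather than omitted, and every
#' numeric field comes from a computed artifact handed in by the caller.
#'
#' Section statuses: content-like sections fail on any mismatch (a
#' functioning setup must log content perfectly); timing sections warn when
#' the SD of the discrepancies exceeds `sd_warn_ms` (means are expected
#' near zero with millisecond-order SD); design sections fail on any rule
#' violation.
#'
#' @param geometry Optional list with fields `distance_cm`, `stimulus`
#'   (data frame: `dimension`, `size_cm`, `angle_deg`) and `eccentricity`
#'   (data frame: `axis`, `offset_cm`, `expected_deg`, `measured_deg`).
#' @param content Optional [compare_event_content()] result.
#' @param response Optional [check_response_plan()] result.
#' @param timing Optional [delta_series()] or list of them (log timing,
#'   duration vs plan, response timing).
#' @param design Optional [validate_design_rules()] result.
#' @param trigger Optional list with any of `content` (a
#'   [compare_event_content()] result or a list with `n_mismatches`,
#'   `n_total`), `jitter` and `delay` ([delta_series()] objects).
#'   The delay entry presumes photodiode and triggers share a clock; the
#'   report flags that assumption.
#' @param sd_warn_ms Timing warn threshold on the SD, in milliseconds.
#' @return A list of class `qa_report`.
#' @export
build_report <- function(geometry = NULL, content = NULL, response = NULL,
                         timing = NULL, design = NULL, trigger = NULL,
                         sd_warn_ms = 5) {
  if (is.null(geometry) && is.null(content) && is.null(response) &&
      is.null(timing) && is.null(design) && is.null(trigger)) {
    abort("at least one computed artifact is required.")
  }
  np <- list(status = "not performed")

  sec_geometry <- if (is.null(geometry)) np else {
    c(list(status = "pass"), geometry)
  }

  sec_content <- if (is.null(content)) np else {
    s <- content$summary
    list(
      status = if (s$n_mismatches > 0) "fail" else "pass",
      n_conditions_tested = s$n_conditions_tested,
      n_events_tested = s$n_events_tested,
      n_mismatches = s$n_mismatches,
      events_per_condition = as.data.frame(content$coverage),
      mismatches = as.data.frame(content$mismatches)
    )
  }

  sec_response <- if (is.null(response)) np else {
    s <- response$summary
    list(
      status = if (s$n_mismatches > 0) "fail" else "pass",
      n_response_types = s$n_response_types,
      responses_per_type = as.data.frame(response$per_type),
      n_inaccurate = s$n_mismatches,
      n_total = s$n_planned,
      mismatches = as.data.frame(response$mismatches)
    )
  }

  sec_timing <- if (is.null(timing)) np else {
    if (inherits(timing, "delta_series")) timing <- list(timing)
    entries <- purrr::map(timing, function(ds) {
      delta_entry(ds, sd_warn_ms)
    })
    names(entries) <- purrr::map_chr(timing, attr, "kind")
    statuses <- purrr::map_chr(entries, "status")
    c(list(status = if (any(statuses == "warn")) "warn" else "pass"),
      entries)
  }

  sec_design <- if (is.null(design)) np else {
    list(
      status = if (all(design$rules$pass)) "pass" else "fail",
      rules = as.data.frame(design$rules),
      combo_counts = if (is.null(design$combo_counts)) NULL else
        as.data.frame(design$combo_counts),
      violations = as.data.frame(design$violations)
    )
  }

  sec_trigger <- if (is.null(trigger)) np else {
    out <- list(status = "pass")
    if (!is.null(trigger$content)) {
      tc <- trigger$content
      if (inherits(tc, "content_report")) {
        tc <- list(n_mismatches = tc$summary$n_mismatches,
                   n_total = tc$summary$n_events_tested)
      }
      out$content <- tc
      if (tc$n_mismatches > 0) out$status <- "fail"
    }
    if (!is.null(trigger$jitter)) {
      out$jitter <- delta_entry(trigger$jitter, sd_warn_ms)
      if (out$jitter$status == "warn" && out$status == "pass") {
        out$status <- "warn"
      }
    }
    if (!is.null(trigger$delay)) {
      out$delay <- delta_entry(trigger$delay, sd_warn_ms)
      out$delay$same_clock_assumed <- TRUE
      drift <- attr(trigger$delay, "drift_s_per_s")
      if (!is.null(drift) && !is.na(drift)) {
        out$delay$drift_s_per_s <- drift
      }
    }
    out
  }

  structure(
    list(
      sections = list(
        geometry = sec_geometry,
        content = sec_content,
        response = sec_response,
        timing = sec_timing,
        design = sec_design,
        trigger = sec_trigger
      ),
      thresholds = list(sd_warn_ms = sd_warn_ms)
    ),
    class = "qa_report"
  )
}

# One timing entry (ms scale) from a delta series.
delta_entry <- function(ds, sd_warn_ms) {
  g <- delta_summary(ds, sd_warn_s = sd_warn_ms / 1000)
  list(
    status = g$status,
    n = g$n,
    mean_ms = g$mean_s * 1000,
    sd_ms = g$sd_s * 1000,
    max_abs_ms = g$max_abs_s * 1000,
    low_n = g$low_n
  )
}

#' @export
print.qa_report <- function(x, ...) {
  cat(render_report(x, format = "markdown"))
  invisible(x)
}

#' @export
glance.qa_report <- function(x, ...) {
  tibble(
    section = names(x$sections),
    status = unname(purrr::map_chr(x$sections, "status"))
  )
}

#' Render a QA report
#'
#' `"json"` is the lossless machine-readable twin (parse it back with
#' [qa_report_from_json()]); `"markdown"` is the human-readable document in
#' the standardized section order. Times are printed in milliseconds.
#'
#' @param report A [build_report()] result.
#' @param format `"markdown"` or `"json"`.
#' @return A character scalar.
#' @export
render_report <- function(report, format = c("markdown", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "qa_report"))
  if (format == "json") {
    return(as.character(jsonlite::toJSON(
      unclass(report), auto_unbox = TRUE, digits = NA, na = "null",
      null = "null"
    )))
  }
  s <- report$sections
  out <- c("# Experimental environment QA report", "")
  fmt_num <- function(v, unit = "") {
    if (is.null(v) || length(v) == 0 || is.na(v)) return("-")
    paste0(formatC(as.numeric(v), format = "fg", digits = 4), unit)
  }
  add_tbl <- function(df) {
    df <- normalize_table(df)
    if (is.null(df) || nrow(df) == 0) return(character(0))
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) {
      paste0("| ", paste(trimws(as.character(r)), collapse = " | "), " |")
    })
    c(hdr, sep, rows, "")
  }
  section <- function(title, body) {
    c(sprintf("## %s", title), "", body, "")
  }

  g <- s$geometry
  out <- c(out, section("Visual features", if (g$status == "not performed") {
    "not performed"
  } else {
    c(
      sprintf("- viewing distance: %s cm", fmt_num(g$distance_cm)),
      "", "Stimulus size (degrees of visual angle):",
      add_tbl(g$stimulus),
      "Eccentricity (degrees of visual angle):",
      add_tbl(g$eccentricity)
    )
  }))

  cs <- s$content
  out <- c(out, section("Event content (controlled events)",
    if (cs$status == "not performed") "not performed" else c(
      sprintf("- status: %s", cs$status),
      sprintf("- conditions tested: %d", cs$n_conditions_tested),
      sprintf("- events tested: %d", cs$n_events_tested),
      sprintf("- incorrectly logged: %d / %d", cs$n_mismatches,
              cs$n_events_tested),
      "", add_tbl(cs$mismatches)
    )
  ))

  rs <- s$response
  out <- c(out, section("Responses (uncontrolled events)",
    if (rs$status == "not performed") "not performed" else c(
      sprintf("- status: %s", rs$status),
      sprintf("- response types: %d", rs$n_response_types),
      sprintf("- inaccurately logged: %d / %d", rs$n_inaccurate,
              rs$n_total),
      "", add_tbl(rs$responses_per_type)
    )
  ))

  ts <- s$timing
  out <- c(out, section("Event timing", if (ts$status == "not performed") {
    "not performed"
  } else {
    body <- sprintf("- status: %s", ts$status)
    for (nm in setdiff(names(ts), "status")) {
      e <- ts[[nm]]
      body <- c(body, sprintf(
        "- %s: mean %s, sd %s, max |delta| %s (n = %d)%s",
        nm, format_ms(e$mean_ms / 1000), format_ms(e$sd_ms / 1000),
        format_ms(e$max_abs_ms / 1000), e$n,
        if (isTRUE(e$low_n)) " [single value: SD not estimable]" else ""
      ))
    }
    body
  }))

  ds <- s$design
  out <- c(out, section("Experimental design compliance",
    if (ds$status == "not performed") "not performed" else c(
      sprintf("- status: %s", ds$status),
      "", add_tbl(ds$rules),
      if (!is.null(ds$combo_counts)) {
        c("Events per condition combination:", add_tbl(ds$combo_counts))
      } else {
        character(0)
      }
    )
  ))

  tr <- s$trigger
  out <- c(out, section("Peripheral triggers",
    if (tr$status == "not performed") "not performed" else {
      body <- sprintf("- status: %s", tr$status)
      if (!is.null(tr$content)) {
        body <- c(body, sprintf("- content mismatches: %d / %d",
                                tr$content$n_mismatches,
                                tr$content$n_total))
      }
      for (nm in intersect(c("jitter", "delay"), names(tr))) {
        e <- tr[[nm]]
        body <- c(body, sprintf(
          "- %s: mean %s, sd %s (n = %d)%s", nm,
          format_ms(e$mean_ms / 1000), format_ms(e$sd_ms / 1000), e$n,
          if (isTRUE(e$same_clock_assumed)) {
            " [assumes photodiode and triggers share a clock]"
          } else {
            ""
          }
        ))
      }
      body
    }
  ))

  paste0(paste(out, collapse = "\n"), "\n")
}

#' Parse a JSON QA report back into a report object
#'
#' Inverse of `render_report(report, "json")`: the JSON twin is lossless,
#' so rendering the parsed object again reproduces the document.
#'
#' @param json JSON string (or path to a JSON file).
#' @return A `qa_report`.
#' @export
qa_report_from_json <- function(json) {
  if (length(json) == 1 && !grepl("^\\s*\\{", json) && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  out <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  structure(out, class = "qa_report")
}

# Accept a data.frame or a parsed-JSON list of row-records.
normalize_table <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    rows <- purrr::map(x, function(r) {
      as_tibble(purrr::map(r, function(v) v %||% NA))
    })
    return(dplyr::bind_rows(rows))
  }
  NULL
}
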