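test_that("comparing a log against itself finds no mismatches", {
  fx <- clean_fixture(n = 12, with_responses = FALSE)
  truth <- fx$log[, c("event_index", attr(fx$log, "factors"))]
  rep <- compare_event_content(fx$log, truth)
  expect_equal(rep$summary$n_mismatches, 0)
  expect_equal(rep$summary$n_events_tested, 12)
  # count conservation
  expect_equal(
    rep$summary$n_mismatches + (rep$summary$n_events_tested -
                                  nrow(rep$mismatches)),
    rep$summary$n_events_tested
  )
})

test_that("a single swapped category is localized to row and field", {
  fx <- clean_fixture(n = 12, with_responses = FALSE)
  truth <- fx$log[, c("event_index", "category", "location")]
  truth$category[4] <- setdiff(c("face", "object"), truth$category[4])
  rep <- compare_event_content(fx$log, truth)
  expect_equal(rep$summary$n_mismatches, 1)
  expect_equal(rep$mismatches$event_index, truth$event_index[4])
  expect_equal(rep$mismatches$field, "category")
})

test_that("injected label errors are recovered exactly (no false positives)", {
  fx <- generate_experiment(std_plan(40, with_responses = FALSE),
                            corruption_spec(label_errors = 3), seed = 19)
  rep <- compare_event_content(fx$log, fixture_truth_table(fx))
  inj <- fx$injected$label_error_rows
  expect_equal(rep$summary$n_mismatches, 3)
  expect_setequal(rep$mismatches$event_index, inj$event_index)
  expect_equal(
    dplyr::arrange(rep$mismatches, event_index)$field,
    dplyr::arrange(inj, event_index)$field
  )
})

test_that("coverage reports conditions tested and lists untested combinations", {
  fx <- clean_fixture(n = 16, with_responses = FALSE)
  stim <- fx$log[fx$log$event_class == "controlled", ]
  subset <- stim[stim$category == "face", ]
  truth <- subset[, c("event_index", "category", "location")]
  rep <- compare_event_content(fx$log, truth)
  expect_lt(rep$summary$n_conditions_tested,
            rep$summary$n_conditions_realized)
  expect_true(all(rep$untested_conditions$category == "object"))
  expect_error(
    compare_event_content(fx$log, tibble::tibble(event_index = 999,
                                                 category = "face")),
    "unknown event_index"
  )
})

test_that("response plan comparison is positional", {
  ok <- check_response_plan(c("a", "a", "b"), c("a", "a", "b"))
  expect_equal(ok$summary$n_mismatches, 0)
  expect_equal(ok$summary$n_planned, 3)

  bad <- check_response_plan(c("a", "b", "b"), c("a", "a", "b"))
  expect_equal(bad$summary$n_mismatches, 1)
  expect_equal(bad$mismatches$position, 2)
  expect_equal(bad$mismatches$type, "wrong key")
})

test_that("a planned double press logged once is flagged as a missing repeat", {
  plan <- tibble::tibble(key = c("a", "b"), presses = c(2L, 1L))
  rep <- check_response_plan(c("a", "b"), plan)
  expect_equal(rep$summary$n_mismatches, 1)
  expect_equal(rep$mismatches$type, "missing repeat")
})

test_that("extra logged responses count as unexpected", {
  rep <- check_response_plan(c("a", "b", "x"), c("a", "b"))
  expect_equal(rep$summary$n_mismatches, 1)
  expect_equal(rep$mismatches$type, "unexpected")
})

test_that("responses from the log rows are ordered by onset", {
  fx <- clean_fixture(n = 6)
  rep <- check_response_plan(
    fx$log, tibble::tibble(key = rep(c("f", "j"), 3), presses = 1L)
  )
  expect_equal(rep$summary$n_mismatches, 0)
  expect_equal(rep$summary$n_planned, 6)
})

test_that("balanced designs validate and imbalances are localized", {
  fx <- clean_fixture(n = 12, with_responses = FALSE) # 3 per combo
  rules <- design_rules(expected_counts = tidyr::expand_grid(
    category = c("face", "object"), location = c("left", "right"),
    n_expected = 3L
  ))
  rep <- validate_design_rules(fx$log, rules)
  expect_true(all(rep$rules$pass))
  expect_true(all(rep$combo_counts$n_observed == 3))
  expect_equal(rep$rules$n_compliant, 12)

  # mislocate one face event: two combos now deviate (2 and 4)
  log2 <- fx$log
  i <- which(log2$category == "face" & log2$location == "left")[1]
  log2$location[i] <- "right"
  rep2 <- validate_design_rules(log2, rules)
  expect_false(rep2$rules$pass)
  expect_setequal(
    rep2$combo_counts$n_observed[rep2$combo_counts$n_observed != 3],
    c(2L, 4L)
  )
})

test_that("order rule flags runs longer than k at the run start", {
  seqs <- c("a", "b", "a", "a", "a", "a", "a", "b", "a")
  log <- tibble::tibble(
    event_index = seq_along(seqs), onset_s = seq_along(seqs),
    category = seqs, event_class = "controlled"
  )
  # brute-force oracle for the longest-run start
  runs <- rle(seqs)
  start_oracle <- cumsum(c(1, head(runs$lengths, -1)))[
    which(runs$lengths > 3)
  ]
  rep <- validate_design_rules(
    log, design_rules(max_run = list(factor = "category", k = 3))
  )
  expect_false(rep$rules$pass)
  expect_equal(rep$violations$location, start_oracle)
  expect_equal(rep$rules$n_compliant, length(seqs) - (5 - 3))

  expect_error(
    validate_design_rules(
      log, design_rules(max_run = list(factor = "nope", k = 2))
    ),
    "unknown factor"
  )
})
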