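Package: eventqa
Title: Quality Assurance for Event-Based Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Toolkit for benchmarking the experimental environment of
    event-based (stimulus/response) experiments. Parses physical
    ground-truth signals (photodiode luminance traces, keypress audio,
    peripheral trigger streams) into event timestamps, quantifies
    timing discrepancies between the physical record and the
    experiment log (per-event timestamping inaccuracy, observed versus
    planned durations, trigger jitter and delay), validates logged
    event content and design compliance against the planned design,
    computes stimulus geometry in degrees of visual angle, assembles a
    standardized quality-assurance report, and simulates the impact of
    label-shuffle and onset-jitter corruptions on two-sample
    t-statistics for ERP amplitude and reaction-time measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
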