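Package: scedrand
Title: Randomization Tests and Quantified Visual Analysis for Replicated
    Single-Case Experimental Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for replicated randomized single-case
    experimental designs (SCED) with daily-measured bounded ordinal
    outcomes: enumeration and stratified randomization of phase designs
    (baseline/treatment/follow-up partitions of a fixed-length course),
    scoring and validation of daily text-message items, quantified visual
    analysis (level, trend, variability, immediacy, percent of
    overlapping data), exhaustive randomization tests over admissible
    intervention start points with Edgington additive p-value combination
    across cases, Tau-U nonoverlap effect sizes with baseline-trend
    control, questionnaire scoring, and a synthetic-cohort generator with
    serial dependence, delayed gradual treatment effects and missingness
    so the whole pipeline can be exercised without raw trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
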