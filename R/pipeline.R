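default_run_config <- function() {
  list(
    design = list(
      total_days = 96L, treatment_days = 56L,
      baseline_min = 7L, baseline_max = 26L,
      strata = list(c(7L, 11L), c(12L, 19L), c(20L, 26L))
    ),
    generator = list(
      baseline_level = 12, effect_size = 10, onset_delay_days = 21,
      ramp_days = 35, effect_shape = "ramp", ar_coefficient = 0.4,
      noise_sd = 3, missing_rate = 0.237
    ),
    analysis = list(
      direction = "greater", tie_rule = "strict", scenario_set = "all",
      tau_u_trend_correction = TRUE, trend_method = "ols",
      immediacy_window = 3L, reverse_value_action = FALSE
    ),
    n_participants = 4L,
    seed = 1L
  )
}

#' Read a run configuration file
#'
#' YAML (or JSON) with optional blocks `design`, `generator`,
#' `analysis`, and top-level `n_participants` and `seed`; anything
#' omitted falls back to the package defaults. A commented example ships
#' at `system.file("extdata", "example_config.yaml", package =
#' "scedrand")`.
#'
#' @param path Path to the config file, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (block in intersect(names(user), c("design", "generator", "analysis"))) {
      cfg[[block]] <- modifyList(cfg[[block]], user[[block]])
    }
    for (key in intersect(names(user), c("n_participants", "seed"))) {
      cfg[[key]] <- user[[key]]
    }
  }
  cfg
}

config_space <- function(cfg) {
  d <- cfg$design
  design_space(d$total_days, d$treatment_days, d$baseline_min, d$baseline_max,
               d$strata)
}

config_generator <- function(cfg) {
  g <- cfg$generator
  generator_config(
    baseline_level = g$baseline_level, effect_size = g$effect_size,
    onset_delay_days = g$onset_delay_days, ramp_days = g$ramp_days,
    effect_shape = g$effect_shape, ar_coefficient = g$ar_coefficient,
    noise_sd = g$noise_sd, missing_rate = g$missing_rate
  )
}

config_echo <- function(cfg) {
  flat <- unlist(cfg)
  paste0("# ", names(flat), " = ", as.character(flat))
}

#' Simulate a cohort and write the raw daily CSV plus design sidecar
#'
#' @param out_csv Path for the raw daily-response CSV.
#' @param designs_csv Path for the design sidecar CSV.
#' @param config Run-config list from [read_run_config()].
#' @param n,seed Optional overrides of the config's `n_participants`
#'   and `seed`.
#' @return The simulated `sced_cohort`, invisibly.
#' @export
sced_simulate <- function(out_csv, designs_csv, config = read_run_config(),
                          n = NULL, seed = NULL) {
  n <- n %||% config$n_participants
  seed <- seed %||% config$seed
  cohort <- simulate_cohort(n, config_space(config), config_generator(config), seed)
  readr::write_csv(cohort_to_responses(cohort), out_csv, na = "")
  write_designs_csv(cohort$designs, designs_csv)
  invisible(cohort)
}

#' Score a raw daily CSV into the scored CSV dialect
#'
#' @param in_csv Raw daily-response CSV (see [read_daily_csv()]).
#' @param out_csv Output path for the scored CSV.
#' @param designs_csv Design sidecar; adds the phase column.
#' @param config Run-config list (supplies the item-5 reversal flag).
#' @return The scored tibble, invisibly.
#' @export
sced_score <- function(in_csv, out_csv, designs_csv, config = read_run_config()) {
  responses <- read_daily_csv(in_csv)
  scored <- score_daily(responses, config$analysis$reverse_value_action)
  designs <- read_designs_csv(designs_csv)
  write_scored_csv(scored, out_csv, designs)
  invisible(scored)
}

#' Quantified visual analysis of a scored CSV
#'
#' Writes the cohort change table (mean level change, POD, immediacy per
#' outcome and phase transition), prefixed by a config echo, and
#' optionally per-participant phase plots.
#'
#' @param scored_csv Scored daily CSV.
#' @param designs_csv Design sidecar CSV.
#' @param out_csv Output table path.
#' @param config Run-config list.
#' @param plot_dir Optional directory for per-participant plots.
#' @return The analysis list from [analyze_cohort()], invisibly.
#' @export
sced_analyze <- function(scored_csv, designs_csv, out_csv,
                         config = read_run_config(), plot_dir = NULL) {
  scored <- readr::read_csv(scored_csv, show_col_types = FALSE, progress = FALSE)
  designs <- read_designs_csv(designs_csv)
  cohort <- list(daily = scored, designs = designs)
  res <- analyze_cohort(
    cohort,
    trend_method = config$analysis$trend_method,
    ties = config$analysis$tie_rule,
    window_k = config$analysis$immediacy_window
  )
  writeLines(config_echo(config), out_csv)
  readr::write_csv(res$changes, out_csv, na = "", append = TRUE, col_names = TRUE)
  if (!is.null(plot_dir)) {
    dir.create(plot_dir, showWarnings = FALSE, recursive = TRUE)
    for (pid in designs$participant_id) {
      p <- plot_daily_series(
        scored[scored$participant_id == pid, ],
        design_for(designs, pid)
      )
      ggplot2::ggsave(
        file.path(plot_dir, paste0(pid, ".png")), p,
        width = 8, height = 6, dpi = 150
      )
    }
  }
  invisible(res)
}

#' Randomization tests and Tau-U from a scored CSV
#'
#' Writes a JSON report with the per-participant observed statistic,
#' full null distribution, p value, Tau-U, the combined p, and every
#' decision flag (sidedness, tie rule, scenario set, Tau-U variant).
#'
#' @param scored_csv Scored daily CSV.
#' @param designs_csv Design sidecar CSV.
#' @param out_json Output JSON path.
#' @param config Run-config list.
#' @return The [run_inference()] list, invisibly.
#' @export
sced_randtest <- function(scored_csv, designs_csv, out_json,
                          config = read_run_config()) {
  scored <- readr::read_csv(scored_csv, show_col_types = FALSE, progress = FALSE)
  designs <- read_designs_csv(designs_csv)
  cohort <- list(daily = scored, designs = designs)
  res <- run_inference(
    cohort, config_space(config),
    direction = config$analysis$direction,
    scenario_set = config$analysis$scenario_set,
    correct_baseline_trend = config$analysis$tau_u_trend_correction
  )
  report <- list(
    config = config,
    flags = res$flags,
    table = res$table,
    null_distributions = lapply(res$results, function(r) r$null_stats),
    combined = list(
      sum_s = res$combined$sum_s, combined_p = res$combined$combined_p,
      n_tests = res$combined$n_tests
    )
  )
  jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Score a questionnaire CSV into a four-time-point change table
#'
#' @param in_csv Wide questionnaire CSV (`participant_id`, `time_point`,
#'   `questionnaire`, `item_1..item_k`).
#' @param out_csv Output path.
#' @return The change table, invisibly.
#' @export
sced_questionnaires <- function(in_csv, out_csv) {
  records <- readr::read_csv(in_csv, show_col_types = FALSE, progress = FALSE)
  out <- change_table(score_questionnaires(records))
  readr::write_csv(out, out_csv, na = "")
  invisible(out)
}

#' Run the whole pipeline into a report directory
#'
#' Simulate (or reuse) a cohort, score it, run the quantified visual
#' analysis and the randomization tests, and collect every table, the
#' config echo and a manifest in one directory. Bit-for-bit reproducible
#' under a fixed seed (plots excluded).
#'
#' @param out_dir Report directory (created if needed).
#' @param config Run-config list.
#' @param raw_csv Optional existing raw daily CSV (with `designs_csv`)
#'   instead of simulating.
#' @param designs_csv Design sidecar when `raw_csv` is given.
#' @param plots Emit per-participant phase plots.
#' @return Path to the manifest, invisibly.
#' @export
sced_report <- function(out_dir, config = read_run_config(),
                        raw_csv = NULL, designs_csv = NULL, plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    raw = file.path(out_dir, "daily_raw.csv"),
    designs = file.path(out_dir, "designs.csv"),
    scored = file.path(out_dir, "daily_scored.csv"),
    analysis = file.path(out_dir, "visual_analysis.csv"),
    randtest = file.path(out_dir, "randomization_tests.json"),
    config = file.path(out_dir, "config_echo.yaml"),
    manifest = file.path(out_dir, "manifest.json")
  )
  if (is.null(raw_csv)) {
    sced_simulate(paths$raw, paths$designs, config)
  } else {
    file.copy(raw_csv, paths$raw, overwrite = TRUE)
    file.copy(designs_csv, paths$designs, overwrite = TRUE)
  }
  sced_score(paths$raw, paths$scored, paths$designs, config)
  sced_analyze(paths$scored, paths$designs, paths$analysis, config,
               plot_dir = if (plots) file.path(out_dir, "plots") else NULL)
  sced_randtest(paths$scored, paths$designs, paths$randtest, config)
  yaml::write_yaml(config, paths$config)
  manifest <- list(
    created = "scedrand pipeline",
    seed = config$seed,
    files = lapply(paths[c("raw", "designs", "scored", "analysis", "randtest", "config")],
                   basename)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths$manifest)
}
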