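#' Bundled questionnaire scoring specifications
#'
#' Specs are data, not code: the bundled table defines, for each
#' secondary-outcome questionnaire, the item count, item range,
#' aggregation (sum or mean) and the resulting score range.
#'
#' * `hapys` - health anxiety by proxy, 26 items 0-4, sum 0-104
#' * `hapys_impact` - impact section, 6 items 0-3, sum 0-18
#' * `acrs_protect` - overprotective behavior, 13 items 0-4, mean 0-4
#' * `acrs_monitor` - monitoring behavior, 4 items 0-4, mean 0-4
#' * `pcs_p` - pain catastrophizing (parent), 13 items 0-4, sum 0-52
#' * `wi6r` - illness worry, 6 items 0-4, sum 0-24
#'
#' @param path Optional path to an alternative spec CSV.
#' @return Tibble with columns `name`, `n_items`, `item_min`,
#'   `item_max`, `aggregation`, `score_min`, `score_max`.
#' @export
questionnaire_specs <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "questionnaire_specs.csv", package = "scedrand")
  specs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  bad <- ifelse(
    specs$aggregation == "sum",
    specs$score_max != specs$n_items * specs$item_max,
    specs$score_max != specs$item_max
  )
  if (any(bad)) {
    stop_config(paste("inconsistent score_max for:", paste(specs$name[bad], collapse = ", ")))
  }
  specs
}

time_point_levels <- c("baseline", "start", "end_of_treatment", "follow_up")

#' Score questionnaire assessment records
#'
#' Takes wide assessment records (one row per participant, time point
#' and questionnaire, with item responses in `item_1..item_k`) and
#' returns total scores per the questionnaire's spec. Every item must be
#' present and within range; missing items are an error because the
#' scoring rules define no missing-data handling.
#'
#' @param records Tibble with columns `participant_id`, `time_point`
#'   (one of baseline, start, end_of_treatment, follow_up),
#'   `questionnaire`, and `item_1`..`item_k`.
#' @param specs Spec table from [questionnaire_specs()].
#' @return Tibble `participant_id`, `time_point`, `questionnaire`,
#'   `score`.
#' @export
score_questionnaires <- function(records, specs = questionnaire_specs()) {
  stopifnot(all(c("participant_id", "time_point", "questionnaire") %in% names(records)))
  unknown_tp <- setdiff(unique(records$time_point), time_point_levels)
  if (length(unknown_tp) > 0) {
    stop_validation(paste("unknown time point(s):", paste(unknown_tp, collapse = ", ")))
  }
  dup <- duplicated(records[c("participant_id", "time_point", "questionnaire")])
  if (any(dup)) {
    d <- records[dup, ][1, ]
    stop_validation(sprintf(
      "duplicate record: participant %s, %s, %s",
      d$participant_id, d$time_point, d$questionnaire
    ))
  }
  scores <- vapply(seq_len(nrow(records)), function(i) {
    row <- records[i, ]
    spec <- specs[specs$name == row$questionnaire, ]
    if (nrow(spec) != 1) {
      stop_validation(sprintf("unknown questionnaire '%s'", row$questionnaire))
    }
    items <- as.numeric(row[paste0("item_", seq_len(spec$n_items))])
    if (anyNA(items)) {
      stop_validation(sprintf(
        "missing item(s) for participant %s, %s, %s",
        row$participant_id, row$questionnaire, row$time_point
      ))
    }
    if (any(items < spec$item_min | items > spec$item_max)) {
      stop_validation(sprintf(
        "item out of range %d..%d for participant %s, %s",
        spec$item_min, spec$item_max, row$participant_id, row$questionnaire
      ))
    }
    if (spec$aggregation == "sum") sum(items) else mean(items)
  }, numeric(1))
  tibble(
    participant_id = records$participant_id,
    time_point = records$time_point,
    questionnaire = records$questionnaire,
    score = scores
  )
}

#' Questionnaire scores across the four assessment points
#'
#' Reshapes scored records into one row per participant and
#' questionnaire with a column per time point (baseline, start of
#' treatment, end of treatment, follow-up) plus the baseline-to-follow-up
#' change.
#'
#' @param scores Tibble from [score_questionnaires()].
#' @return Wide tibble with columns `questionnaire`, `participant_id`,
#'   the four time points, and `change` (follow_up - baseline).
#' @export
change_table <- function(scores) {
  wide <- tidyr::pivot_wider(
    scores,
    names_from = "time_point", values_from = "score"
  )
  for (tp in time_point_levels) {
    if (!tp %in% names(wide)) wide[[tp]] <- NA_real_
  }
  wide <- wide[c("questionnaire", "participant_id", time_point_levels)]
  wide$change <- wide$follow_up - wide$baseline
  dplyr::arrange(wide, .data$questionnaire, .data$participant_id)
}
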