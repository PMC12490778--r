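#' Recode a raw daily item response to the analysis scale
#'
#' Daily items are answered on a 1-10 scale ("does not describe it at
#' all" ... "describes it very well") but analyzed on 0-9: the recode is
#' a shift by one.
#'
#' @param raw Integer vector of raw responses in 1..10 (NA allowed).
#' @return Integer vector in 0..9.
#' @export
#' @examples
#' recode_item(c(1, 5, 10)) # 0 4 9
recode_item <- function(raw) {
  bad <- !is.na(raw) & (raw < 1 | raw > 10 | raw != round(raw))
  if (any(bad)) {
    stop_validation(sprintf(
      "item response outside 1..10: %s", paste(unique(raw[bad]), collapse = ", ")
    ))
  }
  as.integer(raw) - 1L
}

daily_required_cols <- c("participant_id", "day_index",
                         paste0("item", 1:5), "same_day")

validate_daily_responses <- function(responses) {
  missing_cols <- setdiff(daily_required_cols, names(responses))
  if (length(missing_cols) > 0) {
    stop_validation(paste("missing required columns:", paste(missing_cols, collapse = ", ")))
  }
  dup <- duplicated(responses[c("participant_id", "day_index")])
  if (any(dup)) {
    d <- responses[dup, c("participant_id", "day_index")][1, ]
    stop_validation(sprintf(
      "duplicate (participant, day): participant %s day %s (row %d)",
      d$participant_id, d$day_index, which(dup)[1]
    ))
  }
  if (any(!is.na(responses$day_index) & responses$day_index < 1)) {
    stop_validation("day_index must be a positive integer")
  }
  for (it in paste0("item", 1:5)) {
    v <- responses[[it]]
    bad <- !is.na(v) & (v < 1 | v > 10 | v != round(v))
    if (any(bad)) {
      i <- which(bad)[1]
      stop_validation(sprintf(
        "invalid %s = %s for participant %s, day %s",
        it, v[i], responses$participant_id[i], responses$day_index[i]
      ))
    }
  }
  invisible(responses)
}

#' Score daily text-message responses
#'
#' Items 1-3 probe daily anxiety and are recoded to 0-9 and summed
#' (range 0-27); the sum is missing whenever any of the three items is
#' missing (no partial rescaling). Item 4 (impact of anxiety) and item 5
#' (value-based action) are recoded and kept as single 0-9 scores.
#' Responses not answered on the day they were sent (`same_day = FALSE`)
#' are invalid and scored wholly missing.
#'
#' Item 5 is oriented opposite to the anxiety items: higher means more of
#' the desired behavior. By default the recoded value is stored unchanged
#' and the opposite orientation is handled by the analysis direction
#' flags; `reverse_value_action = TRUE` additionally applies the
#' arithmetic reversal `9 - x`.
#'
#' @param responses Tibble of raw responses with columns
#'   `participant_id`, `day_index`, `item1`..`item5`, `same_day`.
#' @param reverse_value_action Apply `9 - x` to the recoded item 5.
#' @return Tibble with columns `participant_id`, `day_index`,
#'   `anxiety_sum` (0-27), `impact` (0-9), `value_action` (0-9); missing
#'   where invalid or unanswered.
#' @export
score_daily <- function(responses, reverse_value_action = FALSE) {
  validate_daily_responses(responses)
  items <- lapply(paste0("item", 1:5), function(it) recode_item(responses[[it]]))
  valid <- !is.na(responses$same_day) & responses$same_day
  anx <- items[[1]] + items[[2]] + items[[3]]
  va <- if (reverse_value_action) 9L - items[[5]] else items[[5]]
  tibble(
    participant_id = responses$participant_id,
    day_index = as.integer(responses$day_index),
    anxiety_sum = ifelse(valid, anx, NA_integer_),
    impact = ifelse(valid, items[[4]], NA_integer_),
    value_action = ifelse(valid, va, NA_integer_)
  )
}

#' Missing daily measures per participant and overall
#'
#' A day counts as missing when it carries no valid score at all: the
#' text message was never answered, was answered on a later day, or the
#' row is absent. Each participant is expected to contribute one measure
#' per day of their course.
#'
#' @param scored Tibble from [score_daily()] (columns `participant_id`,
#'   `day_index`, `anxiety_sum`, `impact`, `value_action`).
#' @param designs Tibble with one row per participant: `participant_id`
#'   and `total_days` (as written by [write_designs_csv()]).
#' @return Tibble with per-participant rows plus an `"overall"` row:
#'   `participant_id`, `n_expected`, `n_missing`, `percent_missing`
#'   (one decimal).
#' @export
missingness_report <- function(scored, designs) {
  missing_design <- setdiff(unique(scored$participant_id), designs$participant_id)
  if (length(missing_design) > 0) {
    stop_config(paste("no design for participant(s):",
                      paste(missing_design, collapse = ", ")))
  }
  per <- lapply(seq_len(nrow(designs)), function(i) {
    pid <- designs$participant_id[i]
    n_expected <- designs$total_days[i]
    rows <- scored[scored$participant_id == pid, ]
    observed <- !is.na(rows$anxiety_sum) | !is.na(rows$impact) | !is.na(rows$value_action)
    n_obs_days <- length(unique(rows$day_index[observed]))
    tibble(
      participant_id = as.character(pid),
      n_expected = as.integer(n_expected),
      n_missing = as.integer(n_expected - n_obs_days)
    )
  })
  out <- dplyr::bind_rows(per)
  out <- dplyr::bind_rows(out, tibble(
    participant_id = "overall",
    n_expected = sum(out$n_expected),
    n_missing = sum(out$n_missing)
  ))
  out$percent_missing <- round(100 * out$n_missing / out$n_expected, 1)
  out
}

#' Read a long-format daily-response CSV
#'
#' Expected columns: `participant_id`, `day_index`, `item1`..`item5`,
#' and either a logical `same_day` or a pair `sent_date`/`answered_date`
#' from which it is derived. Unknown columns are kept with a warning;
#' malformed rows abort with a row-numbered message.
#'
#' @param path Path to a CSV file.
#' @return Validated tibble of daily responses.
#' @export
read_daily_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("day_index", paste0("item", 1:5))) {
    if (!col %in% names(x)) next
    v <- suppressWarnings(as.numeric(as.character(x[[col]])))
    newly_na <- is.na(v) & !is.na(x[[col]])
    if (any(newly_na)) {
      stop_validation(sprintf(
        "non-numeric %s at row(s) %s", col,
        paste(head(which(newly_na), 5), collapse = ", ")
      ))
    }
    x[[col]] <- v
  }
  if (!"same_day" %in% names(x) &&
      all(c("sent_date", "answered_date") %in% names(x))) {
    x$same_day <- !is.na(x$answered_date) &
      as.Date(x$answered_date) == as.Date(x$sent_date)
  }
  extra <- setdiff(names(x), c(daily_required_cols, "sent_date", "answered_date"))
  if (length(extra) > 0) {
    warn(paste("ignoring unknown columns:", paste(extra, collapse = ", ")))
  }
  if (nrow(x) > 0 && any(x$day_index != round(x$day_index), na.rm = TRUE)) {
    stop_validation(sprintf(
      "non-integer day_index at row(s) %s",
      paste(which(x$day_index != round(x$day_index))[1:5], collapse = ", ")
    ))
  }
  x$same_day <- as.logical(x$same_day)
  validate_daily_responses(x)
  x[daily_required_cols]
}

#' Write scored daily measures to CSV
#'
#' Columns: `participant_id`, `day_index`, `phase` (when designs are
#' supplied), `anxiety_sum`, `impact`, `value_action`. Missing values
#' are written as empty fields, so `read -> write -> read` round-trips.
#'
#' @param scored Tibble from [score_daily()].
#' @param path Output path.
#' @param designs Optional designs tibble (see [write_designs_csv()]);
#'   when given, a `phase` column is added.
#' @return The written tibble, invisibly.
#' @export
write_scored_csv <- function(scored, path, designs = NULL) {
  out <- scored
  if (!is.null(designs)) {
    lab <- purrr::pmap(
      list(out$participant_id, out$day_index),
      function(pid, day) {
        d <- design_for(designs, pid)
        phase_of(day, d)
      }
    )
    out <- dplyr::mutate(out, phase = unlist(lab), .after = "day_index")
  }
  readr::write_csv(out, path, na = "")
  invisible(out)
}

#' Read / write a designs sidecar CSV
#'
#' One row per participant: `participant_id`, `baseline_days`,
#' `treatment_days`, `followup_days`, `total_days`, `stratum`.
#'
#' @param designs Designs tibble.
#' @param path File path.
#' @return The designs tibble (invisibly for the writer).
#' @export
write_designs_csv <- function(designs, path) {
  readr::write_csv(designs, path, na = "")
  invisible(designs)
}

#' @rdname write_designs_csv
#' @export
read_designs_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Look up one participant's phase design in a designs tibble
#' @param designs Designs tibble (see [write_designs_csv()]).
#' @param participant_id Which participant.
#' @return A [phase_design()].
#' @export
design_for <- function(designs, participant_id) {
  row <- designs[designs$participant_id == participant_id, ]
  if (nrow(row) != 1) {
    stop_config(sprintf("no unique design for participant %s", participant_id))
  }
  phase_design(row$baseline_days, row$treatment_days, row$total_days)
}

#' Extract one participant-outcome series as a day-indexed vector
#'
#' Analytics and inference operate on a numeric vector of length
#' `total_days` with `NA` for missing days; this converts the long
#' scored table into that form.
#'
#' @param scored Tibble from [score_daily()].
#' @param participant_id Which participant.
#' @param outcome One of `"anxiety_sum"`, `"impact"`, `"value_action"`.
#' @param design The participant's [phase_design()].
#' @return Numeric vector of length `design$total_days`.
#' @export
series_from_scored <- function(scored, participant_id, outcome, design) {
  outcome <- match.arg(outcome, c("anxiety_sum", "impact", "value_action"))
  rows <- scored[scored$participant_id == participant_id, ]
  values <- rep(NA_real_, design$total_days)
  ok <- rows$day_index >= 1 & rows$day_index <= design$total_days
  values[rows$day_index[ok]] <- rows[[outcome]][ok]
  values
}
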