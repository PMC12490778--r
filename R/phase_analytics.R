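observed_phase <- function(values, design, phase) {
  lab <- phase_labels(design)
  idx <- which(lab %in% phase & !is.na(values))
  tibble(day_index = idx, value = values[idx])
}

#' Descriptive summary of one phase
#'
#' Level (mean), variability (minimum, maximum, range) and trend of the
#' observed values in one phase. The trend is an ordinary least-squares
#' line of value on day index by default; `"split_middle"` gives the
#' traditional visual-analysis alternative (the line through the
#' medians of the two halves of the phase). Missing days are skipped,
#' never interpolated. An empty phase yields an "insufficient data" row
#' (`NA` statistics, note set) rather than an error, so that reports can
#' still render.
#'
#' @param values Numeric day-indexed vector (length `total_days`, `NA`
#'   for missing days).
#' @param design A [phase_design()].
#' @param phase `"A"`, `"B"` or `"C"`.
#' @param trend_method `"ols"` or `"split_middle"`.
#' @return One-row tibble: `phase`, `n_observed`, `mean`, `min`, `max`,
#'   `range`, `trend_slope` (per day), `trend_intercept`, `note`.
#' @export
summarize_phase <- function(values, design, phase,
                            trend_method = c("ols", "split_middle")) {
  trend_method <- match.arg(trend_method)
  obs <- observed_phase(values, design, phase)
  if (nrow(obs) == 0) {
    return(tibble(
      phase = phase, n_observed = 0L, mean = NA_real_, min = NA_real_,
      max = NA_real_, range = NA_real_, trend_slope = NA_real_,
      trend_intercept = NA_real_, note = "insufficient data"
    ))
  }
  slope <- intercept <- NA_real_
  note <- NA_character_
  if (nrow(obs) >= 2) {
    tr <- phase_trend(obs, trend_method)
    slope <- tr[["slope"]]
    intercept <- tr[["intercept"]]
  } else {
    note <- "trend requires >= 2 observed values"
  }
  tibble(
    phase = phase,
    n_observed = nrow(obs),
    mean = mean(obs$value),
    min = min(obs$value),
    max = max(obs$value),
    range = max(obs$value) - min(obs$value),
    trend_slope = slope,
    trend_intercept = intercept,
    note = note
  )
}

phase_trend <- function(obs, trend_method) {
  if (trend_method == "ols") {
    fit <- lm(value ~ day_index, data = obs)
    c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
  } else {
    # split-middle: medians of the first and second half of the phase
    # (the middle point is dropped when n is odd)
    n <- nrow(obs)
    h <- floor(n / 2)
    first <- obs[seq_len(h), ]
    second <- obs[seq.int(n - h + 1L, n), ]
    x1 <- median(first$day_index); y1 <- median(first$value)
    x2 <- median(second$day_index); y2 <- median(second$value)
    if (x2 == x1) return(c(slope = NA_real_, intercept = NA_real_))
    slope <- (y2 - y1) / (x2 - x1)
    c(slope = slope, intercept = y1 - slope * x1)
  }
}

#' Mean level change between two phases
#'
#' Signed difference of phase means, later minus earlier, so that for
#' anxiety-type outcomes a negative value is an improvement.
#'
#' @inheritParams summarize_phase
#' @param from_phase,to_phase Phase labels; the change is
#'   `mean(to) - mean(from)` over observed values.
#' @return A single numeric (NA with a warning-free "insufficient data"
#'   attribute when a phase has no observed values).
#' @export
level_change <- function(values, design, from_phase, to_phase) {
  from <- observed_phase(values, design, from_phase)
  to <- observed_phase(values, design, to_phase)
  if (nrow(from) == 0 || nrow(to) == 0) return(NA_real_)
  mean(to$value) - mean(from$value)
}

#' Percent of overlapping data (POD) between two phases
#'
#' POD counts the later-phase data points not improved beyond the most
#' favorable value of the previous phase. For outcomes where improvement
#' is a decrease (anxiety, impact), a later point overlaps when it lies
#' strictly above the previous phase's minimum; where improvement is an
#' increase (value-based action), when it lies strictly below the
#' previous phase's maximum. 0% between phases A and B indicates a
#' perfect treatment effect. Points exactly at the previous extreme are
#' counted as not overlapping by default (`ties = "strict"`);
#' `ties = "overlap"` counts them as overlap.
#'
#' @inheritParams level_change
#' @param direction `"decrease"` or `"increase"` - which way is
#'   improvement.
#' @param ties `"strict"` (ties do not overlap) or `"overlap"`.
#' @return One-row tibble: `from_phase`, `to_phase`, `n_later_observed`,
#'   `n_overlapping`, `pod_percent` (exact), `pod_display` (whole
#'   percent), `ties`, `note`.
#' @export
pod <- function(values, design, from_phase, to_phase,
                direction = c("decrease", "increase"),
                ties = c("strict", "overlap")) {
  direction <- match.arg(direction)
  ties <- match.arg(ties)
  from <- observed_phase(values, design, from_phase)
  to <- observed_phase(values, design, to_phase)
  if (nrow(from) == 0 || nrow(to) == 0) {
    return(tibble(
      from_phase = from_phase, to_phase = to_phase,
      n_later_observed = nrow(to), n_overlapping = NA_integer_,
      pod_percent = NA_real_, pod_display = NA_real_, ties = ties,
      note = "insufficient data"
    ))
  }
  overlapping <- if (direction == "decrease") {
    thr <- min(from$value)
    if (ties == "strict") to$value > thr else to$value >= thr
  } else {
    thr <- max(from$value)
    if (ties == "strict") to$value < thr else to$value <= thr
  }
  pct <- 100 * sum(overlapping) / nrow(to)
  tibble(
    from_phase = from_phase, to_phase = to_phase,
    n_later_observed = nrow(to), n_overlapping = sum(overlapping),
    pod_percent = pct, pod_display = round(pct), ties = ties,
    note = NA_character_
  )
}

#' Immediacy of effect at the treatment entry
#'
#' Difference between the mean of the first `window_k` observed
#' treatment-phase values and the mean of the last `window_k` observed
#' baseline values; same sign convention as [level_change()]. A small
#' immediacy alongside a substantial full-phase level change is the
#' signature of a delayed effect.
#'
#' @inheritParams level_change
#' @param window_k Number of observed points on each side (default 3).
#' @return A single numeric; `NA` if either side has fewer than
#'   `window_k` observed values.
#' @export
immediacy <- function(values, design, window_k = 3L) {
  a <- observed_phase(values, design, "A")
  b <- observed_phase(values, design, "B")
  if (nrow(a) < window_k || nrow(b) < window_k) return(NA_real_)
  mean(head(b$value, window_k)) - mean(tail(a$value, window_k))
}

outcome_directions <- c(
  anxiety_sum = "decrease", impact = "decrease", value_action = "increase"
)

#' Full quantified visual analysis for one participant
#'
#' Assembles, for each of the three daily outcomes, the per-phase
#' summaries, the A-to-B and B-to-C mean level changes and POD, and the
#' immediacy of effect. The improvement direction is decrease for
#' anxiety and impact and increase for value-based action.
#'
#' @param scored_one Scored tibble ([score_daily()] output) restricted
#'   to one participant.
#' @param design The participant's [phase_design()].
#' @param trend_method,ties,window_k Passed through to the feature
#'   functions.
#' @return List with `phase_summaries`, `changes` (level change, POD and
#'   immediacy per outcome and transition), and the flags used.
#' @export
analyze_participant <- function(scored_one, design,
                                trend_method = c("ols", "split_middle"),
                                ties = c("strict", "overlap"),
                                window_k = 3L) {
  trend_method <- match.arg(trend_method)
  ties <- match.arg(ties)
  pid <- unique(scored_one$participant_id)
  stopifnot(length(pid) == 1)
  outcomes <- names(outcome_directions)
  summaries <- list()
  changes <- list()
  for (oc in outcomes) {
    v <- series_from_scored(scored_one, pid, oc, design)
    summaries[[oc]] <- dplyr::bind_rows(lapply(
      c("A", "B", "C"),
      function(ph) summarize_phase(v, design, ph, trend_method)
    ))
    summaries[[oc]] <- dplyr::mutate(summaries[[oc]],
      participant_id = pid, outcome = oc, .before = 1
    )
    p_ab <- pod(v, design, "A", "B", outcome_directions[[oc]], ties)
    p_bc <- pod(v, design, "B", "C", outcome_directions[[oc]], ties)
    changes[[oc]] <- tibble(
      participant_id = pid,
      outcome = oc,
      change_a_b = level_change(v, design, "A", "B"),
      change_b_c = level_change(v, design, "B", "C"),
      pod_a_b = p_ab$pod_percent,
      pod_b_c = p_bc$pod_percent,
      immediacy = immediacy(v, design, window_k)
    )
  }
  list(
    participant_id = pid,
    phase_summaries = dplyr::bind_rows(summaries),
    changes = dplyr::bind_rows(changes),
    flags = list(trend_method = trend_method, ties = ties, window_k = window_k)
  )
}

#' Quantified visual analysis across a cohort
#'
#' Per-participant level changes, POD and immediacy laid out like a
#' mean-level-change / percent-overlap table: one row per participant
#' and outcome with A-to-B and B-to-C columns. Display rounding follows
#' report precision (one decimal for mean changes, whole percent for
#' POD); underlying full-precision values are retained.
#'
#' @param cohort An `sced_cohort`, or a list with `daily` and `designs`.
#' @inheritParams analyze_participant
#' @return List with `changes` (cohort table), `phase_summaries`, and
#'   `flags`.
#' @export
analyze_cohort <- function(cohort,
                           trend_method = c("ols", "split_middle"),
                           ties = c("strict", "overlap"),
                           window_k = 3L) {
  trend_method <- match.arg(trend_method)
  ties <- match.arg(ties)
  pids <- cohort$designs$participant_id
  reports <- lapply(pids, function(pid) {
    analyze_participant(
      cohort$daily[cohort$daily$participant_id == pid, ],
      design_for(cohort$designs, pid),
      trend_method, ties, window_k
    )
  })
  changes <- dplyr::bind_rows(lapply(reports, `[[`, "changes"))
  changes <- dplyr::mutate(
    changes,
    change_a_b_display = round(.data$change_a_b, 1),
    change_b_c_display = round(.data$change_b_c, 1),
    pod_a_b_display = round(.data$pod_a_b),
    pod_b_c_display = round(.data$pod_b_c)
  )
  list(
    changes = changes,
    phase_summaries = dplyr::bind_rows(lapply(reports, `[[`, "phase_summaries")),
    flags = list(trend_method = trend_method, ties = ties, window_k = window_k)
  )
}
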