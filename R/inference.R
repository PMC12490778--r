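#' Mean-difference test statistic for the randomization test
#'
#' MeanA - MeanBC: the mean of the observed baseline values minus the
#' pooled mean of the observed treatment and follow-up values, under a
#' candidate phase design. Treatment and follow-up are pooled because no
#' new intervention is introduced at the follow-up boundary. Positive
#' values mean the outcome fell after treatment entry.
#'
#' @param values Day-indexed numeric vector (`NA` = missing).
#' @param design A [phase_design()].
#' @return A single numeric; `NA` if either side has no observed value.
#' @export
mean_diff_stat <- function(values, design) {
  if (length(values) != design$total_days) {
    stop_validation(sprintf(
      "series has %d days but the design expects %d",
      length(values), design$total_days
    ))
  }
  a <- values[seq_len(design$baseline_days)]
  bc <- values[seq.int(design$baseline_days + 1L, design$total_days)]
  if (all(is.na(a)) || all(is.na(bc))) return(NA_real_)
  mean(a, na.rm = TRUE) - mean(bc, na.rm = TRUE)
}

#' Exact randomization test over admissible treatment entry points
#'
#' Because the baseline length was randomized, an exact test is obtained
#' by recomputing the MeanA - MeanBC statistic on the same observed
#' series under every admissible phase design and ranking the observed
#' design's statistic within that null distribution. With 20 admissible
#' entries the attainable p values are 1/20, 2/20, ..., 1, so the
#' smallest possible p is .05.
#'
#' Ties with the observed statistic count as "as or more extreme"
#' (conservative; guarantees p >= 1/n_scenarios). A candidate design
#' leaving either side with no observed values is dropped from the null
#' set with a warning, reducing `n_scenarios`.
#'
#' @param values Day-indexed numeric vector.
#' @param space A [design_space()]; by default all admissible entries
#'   form the null set (`scenario_set = "all"`);
#'   `scenario_set = "stratum"` restricts it to the observed design's
#'   stratum for sensitivity analysis.
#' @param observed_design The [phase_design()] actually realized.
#' @param direction `"greater"` (one-sided in the improvement direction:
#'   large MeanA - MeanBC means the outcome fell), `"less"`, or
#'   `"two.sided"`.
#' @param scenario_set `"all"` or `"stratum"`.
#' @return An object of class `randomization_result`: list with
#'   `observed_stat`, `null_stats` (tibble keyed by baseline length),
#'   `n_scenarios`, `p_value`, `direction`, `scenario_set`.
#' @export
randomization_test <- function(values, space = design_space(), observed_design,
                               direction = c("greater", "less", "two.sided"),
                               scenario_set = c("all", "stratum")) {
  direction <- match.arg(direction)
  scenario_set <- match.arg(scenario_set)
  stopifnot(inherits(observed_design, "phase_design"))
  designs <- enumerate_designs(space)
  if (!observed_design$baseline_days %in% designs$baseline_days ||
      observed_design$total_days != space$total_days ||
      observed_design$treatment_days != space$treatment_days) {
    stop_config("observed design is not a member of the design space")
  }
  if (scenario_set == "stratum") {
    st <- stratum_of_baseline(observed_design$baseline_days, space)
    designs <- designs[designs$stratum == st, ]
  }
  stats <- vapply(designs$baseline_days, function(b) {
    mean_diff_stat(values, phase_design(b, space$treatment_days, space$total_days))
  }, numeric(1))
  keep <- !is.na(stats)
  if (any(!keep)) {
    warn(sprintf(
      "%d scenario(s) dropped: no observed values on one side (baseline %s)",
      sum(!keep), paste(designs$baseline_days[!keep], collapse = ", ")
    ))
  }
  null_stats <- tibble(
    baseline_days = designs$baseline_days[keep],
    stat = stats[keep]
  )
  obs <- stats[designs$baseline_days == observed_design$baseline_days]
  if (is.na(obs)) stop_validation("observed design has no computable statistic")
  tol <- 1e-12
  extreme <- switch(direction,
    greater = null_stats$stat >= obs - tol,
    less = null_stats$stat <= obs + tol,
    two.sided = abs(null_stats$stat) >= abs(obs) - tol
  )
  structure(
    list(
      observed_stat = obs,
      null_stats = null_stats,
      n_scenarios = nrow(null_stats),
      p_value = sum(extreme) / nrow(null_stats),
      direction = direction,
      scenario_set = scenario_set
    ),
    class = "randomization_result"
  )
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf(
    "<randomization_result> stat = %.3f, p = %s (%d scenarios, %s, %s set)\n",
    x$observed_stat, format_p(x$p_value), x$n_scenarios, x$direction, x$scenario_set
  ))
  invisible(x)
}

#' Combine p values by the Edgington additive method
#'
#' The combined p value is the probability that a sum of `n` independent
#' Uniform(0,1) variables falls at or below the observed sum
#' \eqn{S = \sum p_i} (the Irwin-Hall distribution function):
#' \deqn{P = \frac{1}{n!} \sum_{k=0}^{\lfloor S \rfloor} (-1)^k
#'   \binom{n}{k} (S-k)^n}
#' capped at 1 (the expression can exceed 1 only through floating error
#' near S = n).
#'
#' @param p_values Numeric vector of p values in (0, 1\].
#' @return An object of class `combined_result`: list with
#'   `component_p`, `sum_s`, `combined_p`, `n_tests`.
#' @export
#' @examples
#' edgington_combine(c(0.45, 0.99, 0.35, 0.50))
edgington_combine <- function(p_values) {
  if (length(p_values) < 1) stop_validation("need at least one p value")
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop_validation("p values must lie in (0, 1]")
  }
  n <- length(p_values)
  s <- sum(p_values)
  k <- 0:floor(s)
  combined <- sum((-1)^k * choose(n, k) * (s - k)^n) / factorial(n)
  structure(
    list(
      component_p = p_values,
      sum_s = s,
      combined_p = min(max(combined, 0), 1),
      n_tests = n
    ),
    class = "combined_result"
  )
}

#' @export
print.combined_result <- function(x, ...) {
  cat(sprintf(
    "<combined_result> S = %.3f over %d tests, combined p = %s\n",
    x$sum_s, x$n_tests, format_p(x$combined_p)
  ))
  invisible(x)
}

#' Tau-U nonoverlap effect size with baseline-trend control
#'
#' Kendall-type pairwise comparison of the baseline phase A against the
#' pooled treatment and follow-up phases B+C:
#' `s_cross` sums `sign(value_j - value_i)` over all pairs with i in A
#' and j in B+C; `s_trend_a` does the same over ordered within-baseline
#' pairs, capturing the baseline's internal trend. With
#' `correct_baseline_trend = TRUE` (the default),
#' `tau_u = (s_cross - s_trend_a) / (nA*nBC + nA*(nA-1)/2)`; without
#' correction the plain nonoverlap `tau = s_cross / (nA*nBC)`.
#' Negative values indicate the outcome decreased after treatment entry
#' (improvement, for anxiety-type outcomes). Only observed values enter
#' the pair counts.
#'
#' @param values Day-indexed numeric vector.
#' @param design A [phase_design()].
#' @param correct_baseline_trend Subtract the baseline-trend pairs.
#' @return An object of class `tau_u_result`: list with `s_cross`,
#'   `s_trend_a`, `n_a`, `n_bc`, `tau_u`, `variant`, `note`.
#' @export
tau_u <- function(values, design, correct_baseline_trend = TRUE) {
  lab <- phase_labels(design)
  a <- values[lab == "A"]; a <- a[!is.na(a)]
  bc <- values[lab != "A"]; bc <- bc[!is.na(bc)]
  n_a <- length(a); n_bc <- length(bc)
  variant <- if (correct_baseline_trend) "trend_corrected" else "uncorrected"
  if (n_bc < 1 || n_a < (if (correct_baseline_trend) 2 else 1)) {
    return(structure(
      list(s_cross = NA_real_, s_trend_a = NA_real_, n_a = n_a, n_bc = n_bc,
           tau_u = NA_real_, variant = variant, note = "insufficient data"),
      class = "tau_u_result"
    ))
  }
  s_cross <- sum(sign(rep(bc, each = n_a) - rep(a, times = n_bc)))
  if (correct_baseline_trend) {
    pairs <- which(upper.tri(matrix(0, n_a, n_a)), arr.ind = TRUE)
    s_trend_a <- sum(sign(a[pairs[, 2]] - a[pairs[, 1]]))
    denom <- n_a * n_bc + n_a * (n_a - 1) / 2
    tau <- (s_cross - s_trend_a) / denom
  } else {
    s_trend_a <- 0
    tau <- s_cross / (n_a * n_bc)
  }
  structure(
    list(s_cross = s_cross, s_trend_a = s_trend_a, n_a = n_a, n_bc = n_bc,
         tau_u = tau, variant = variant, note = NA_character_),
    class = "tau_u_result"
  )
}

#' @export
print.tau_u_result <- function(x, ...) {
  cat(sprintf(
    "<tau_u_result> tau = %s (%s; nA = %d, nBC = %d)\n",
    ifelse(is.na(x$tau_u), "NA", sprintf("%.2f", x$tau_u)),
    x$variant, x$n_a, x$n_bc
  ))
  invisible(x)
}

#' Randomization tests and effect sizes across a cohort
#'
#' Runs the per-participant exact randomization test and Tau-U on the
#' daily anxiety outcome and combines the per-participant p values with
#' the Edgington additive method. Output is shaped like a statistical
#' summary table: one row per participant plus an "All combined" row,
#' with p and Tau-U rendered to two decimals (p at or above .995 as
#' ">=.99").
#'
#' @param cohort An `sced_cohort` (or list with `daily` and `designs`).
#' @param space The [design_space()] the baselines were randomized in.
#' @param outcome Which daily outcome to test (default `anxiety_sum`).
#' @param direction,scenario_set Passed to [randomization_test()].
#' @param correct_baseline_trend Passed to [tau_u()].
#' @return List with `table` (formatted tibble), `results`
#'   (per-participant `randomization_result`s), `tau` (per-participant
#'   `tau_u_result`s), `combined` (`combined_result`), `flags`.
#' @export
run_inference <- function(cohort, space = design_space(),
                          outcome = "anxiety_sum",
                          direction = "greater",
                          scenario_set = "all",
                          correct_baseline_trend = TRUE) {
  pids <- cohort$designs$participant_id
  if (length(pids) < 1) stop_config("cohort has no participants")
  results <- list(); taus <- list()
  for (pid in pids) {
    design <- design_for(cohort$designs, pid)
    v <- series_from_scored(cohort$daily, pid, outcome, design)
    results[[pid]] <- randomization_test(v, space, design, direction, scenario_set)
    taus[[pid]] <- tau_u(v, design, correct_baseline_trend)
  }
  p_values <- unname(vapply(results, `[[`, numeric(1), "p_value"))
  combined <- edgington_combine(p_values)
  tau_vals <- unname(vapply(taus, `[[`, numeric(1), "tau_u"))
  table <- tibble(
    participant_id = c(pids, "All combined"),
    observed_stat = c(unname(vapply(results, `[[`, numeric(1), "observed_stat")), NA_real_),
    n_scenarios = c(unname(vapply(results, `[[`, numeric(1), "n_scenarios")), NA_integer_),
    p_value = c(p_values, combined$combined_p),
    p_display = format_p(c(p_values, combined$combined_p)),
    tau_u = c(tau_vals, NA_real_),
    tau_display = c(sprintf("%.2f", tau_vals), NA_character_)
  )
  list(
    table = table,
    results = results,
    tau = taus,
    combined = combined,
    flags = list(
      outcome = outcome, direction = direction, scenario_set = scenario_set,
      tie_rule = "ties count as extreme",
      tau_u_variant = if (correct_baseline_trend) "trend_corrected" else "uncorrected"
    )
  )
}
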