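#' Phase design of a fixed-length single-case course
#'
#' A single-case course of `total_days` days is partitioned into a
#' baseline phase A, a treatment phase B and a follow-up phase C. The
#' randomized quantity is the baseline length; treatment length is fixed,
#' and follow-up absorbs the remainder so every participant's course has
#' the same total duration.
#'
#' @param baseline_days Length of phase A in days.
#' @param treatment_days Length of phase B in days (default 56, an
#'   8-week treatment).
#' @param total_days Total course length (default 96 daily measurements).
#' @return An object of class `phase_design`: a list with
#'   `baseline_days`, `treatment_days`, `followup_days`, `total_days`.
#' @export
#' @examples
#' phase_design(7)
#' phase_design(26)$followup_days # 14
phase_design <- function(baseline_days, treatment_days = 56L, total_days = 96L) {
  baseline_days <- as.integer(baseline_days)
  treatment_days <- as.integer(treatment_days)
  total_days <- as.integer(total_days)
  followup_days <- total_days - baseline_days - treatment_days
  if (baseline_days < 1L || treatment_days < 1L || followup_days < 1L) {
    stop_config(sprintf(
      "invalid phase design: baseline %d + treatment %d leaves follow-up %d of %d days",
      baseline_days, treatment_days, followup_days, total_days
    ))
  }
  structure(
    list(
      baseline_days = baseline_days,
      treatment_days = treatment_days,
      followup_days = followup_days,
      total_days = total_days
    ),
    class = "phase_design"
  )
}

#' @export
print.phase_design <- function(x, ...) {
  cat(sprintf(
    "<phase_design> A=%d B=%d C=%d (total %d days)\n",
    x$baseline_days, x$treatment_days, x$followup_days, x$total_days
  ))
  invisible(x)
}

#' Admissible design space for the randomized baseline length
#'
#' Defines every phase partition the randomization scheme could have
#' produced: a fixed course length, a fixed treatment length, an
#' inclusive range of admissible baseline lengths, and a stratification
#' of that range used for balanced allocation.
#'
#' @param total_days Course length in days.
#' @param treatment_days Treatment-phase length in days.
#' @param baseline_min,baseline_max Inclusive bounds on the baseline
#'   length in days.
#' @param strata List of length-2 integer vectors, ordered, disjoint and
#'   jointly covering `baseline_min:baseline_max`.
#' @return An object of class `design_space`.
#' @export
#' @examples
#' design_space() # the default: 20 admissible treatment entry points
design_space <- function(total_days = 96L,
                         treatment_days = 56L,
                         baseline_min = 7L,
                         baseline_max = 26L,
                         strata = list(c(7L, 11L), c(12L, 19L), c(20L, 26L))) {
  total_days <- as.integer(total_days)
  treatment_days <- as.integer(treatment_days)
  baseline_min <- as.integer(baseline_min)
  baseline_max <- as.integer(baseline_max)
  if (baseline_min > baseline_max) {
    stop_config("empty baseline range: baseline_min exceeds baseline_max")
  }
  if (total_days - treatment_days - baseline_max < 1L) {
    stop_config("treatment too long: no room for follow-up at the longest baseline")
  }
  strata <- lapply(strata, function(s) as.integer(s[1:2]))
  covered <- unlist(lapply(strata, function(s) seq.int(s[1], s[2])))
  if (any(duplicated(covered)) || !setequal(covered, seq.int(baseline_min, baseline_max)) ||
      is.unsorted(covered)) {
    stop_config("strata must be ordered, disjoint and cover the baseline range exactly")
  }
  structure(
    list(
      total_days = total_days,
      treatment_days = treatment_days,
      baseline_min = baseline_min,
      baseline_max = baseline_max,
      strata = strata
    ),
    class = "design_space"
  )
}

#' @export
print.design_space <- function(x, ...) {
  cat(sprintf(
    "<design_space> total %d, treatment %d, baseline %d-%d, %d strata, %d designs\n",
    x$total_days, x$treatment_days, x$baseline_min, x$baseline_max,
    length(x$strata), x$baseline_max - x$baseline_min + 1L
  ))
  invisible(x)
}

stratum_of_baseline <- function(baseline_days, space) {
  for (i in seq_along(space$strata)) {
    s <- space$strata[[i]]
    if (baseline_days >= s[1] && baseline_days <= s[2]) return(i)
  }
  NA_integer_
}

#' Enumerate every admissible phase design
#'
#' One design per admissible baseline length, in ascending order. Under
#' the default space there are 20 admissible treatment entry points, so
#' the smallest attainable randomization-test p value is 1/20 = .05.
#'
#' @param space A [design_space()].
#' @return A tibble with one row per design: `baseline_days`,
#'   `treatment_days`, `followup_days`, `total_days`, `stratum`.
#' @export
#' @examples
#' nrow(enumerate_designs(design_space())) # 20
enumerate_designs <- function(space = design_space()) {
  stopifnot(inherits(space, "design_space"))
  baselines <- seq.int(space$baseline_min, space$baseline_max)
  tibble(
    baseline_days = baselines,
    treatment_days = space$treatment_days,
    followup_days = space$total_days - space$treatment_days - baselines,
    total_days = space$total_days,
    stratum = vapply(baselines, stratum_of_baseline, integer(1), space = space)
  )
}

#' Draw one phase design uniformly within a stratum
#'
#' Baseline lengths are stratified (short / medium / long) and each
#' participant's baseline is drawn uniformly within their assigned
#' stratum, so that strata are filled evenly across the cohort.
#'
#' @param space A [design_space()].
#' @param stratum_index Which stratum to draw from (1-based).
#' @param seed Optional integer seed for a reproducible draw; the global
#'   RNG state is left untouched when given.
#' @return A [phase_design()].
#' @export
#' @examples
#' draw_design(design_space(), 2, seed = 1)
draw_design <- function(space = design_space(), stratum_index, seed = NULL) {
  stopifnot(inherits(space, "design_space"))
  if (stratum_index < 1L || stratum_index > length(space$strata)) {
    stop_config(sprintf("stratum_index %s out of range", stratum_index))
  }
  s <- space$strata[[stratum_index]]
  support <- seq.int(s[1], s[2])
  if (length(support) == 0L) stop_config("empty stratum")
  b <- with_seed_maybe(seed, support[sample.int(length(support), 1L)])
  phase_design(b, space$treatment_days, space$total_days)
}

#' Phase label of a study day
#'
#' Day indexing is 1-based; the intervention starts on the first day of
#' phase B, i.e. day `baseline_days + 1`.
#'
#' @param day_index Integer vector of 1-based day indices.
#' @param design A [phase_design()].
#' @return Character vector of labels in `{"A","B","C"}`.
#' @export
#' @examples
#' phase_of(c(7, 8, 63, 64), phase_design(7))
phase_of <- function(day_index, design) {
  stopifnot(inherits(design, "phase_design"))
  day_index <- as.integer(day_index)
  if (any(day_index < 1L | day_index > design$total_days)) {
    stop_validation(sprintf("day index out of range 1..%d", design$total_days))
  }
  ifelse(
    day_index <= design$baseline_days, "A",
    ifelse(day_index <= design$baseline_days + design$treatment_days, "B", "C")
  )
}

#' Phase labels for every day of a design
#' @param design A [phase_design()].
#' @return Character vector of length `total_days`.
#' @export
phase_labels <- function(design) phase_of(seq_len(design$total_days), design)

#' Cyclic allocation of participants to strata
#'
#' Participants are assigned to strata in enrollment order, cycling
#' 1, 2, ..., K, 1, 2, ... so every stratum receives either
#' `ceiling(n/K)` or `floor(n/K)` participants. Exact equality is only
#' possible when `n` is divisible by the number of strata; otherwise a
#' warning notes the imbalance.
#'
#' @param n Number of participants.
#' @param n_strata Number of strata (default 3).
#' @return Integer vector of stratum indices of length `n`.
#' @export
#' @examples
#' allocate_strata(4)
allocate_strata <- function(n, n_strata = 3L) {
  if (n < 1L) stop_config("need at least one participant")
  if (n %% n_strata != 0L) {
    warn(sprintf("n = %d is not divisible by %d strata; allocation is unbalanced", n, n_strata))
  }
  rep_len(seq_len(n_strata), n)
}
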