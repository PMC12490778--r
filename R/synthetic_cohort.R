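#' Configuration of the synthetic daily-outcome generator
#'
#' The generator emulates the statistical structure the analysis
#' assumes: a bounded ordinal daily outcome with serial dependence, a
#' delayed and gradual treatment effect, and missing days. The latent
#' process is \eqn{x_t = \mu_t + e_t} with AR(1) noise
#' \eqn{e_t = \phi e_{t-1} + \sigma z_t}; the mean path \eqn{\mu_t}
#' stays at `baseline_level` through phase A and the first
#' `onset_delay_days` of phase B, then declines linearly by
#' `effect_size` over `ramp_days` and stays at the post level
#' (`effect_shape = "step"` drops immediately at onset instead).
#' Observed scores are the latent values rounded and clipped to the
#' outcome bounds; each day is independently missing with probability
#' `missing_rate`.
#'
#' @param baseline_level Expected anxiety sum during baseline, on the
#'   0-27 scale.
#' @param effect_size Total expected drop from baseline to post-effect
#'   level, same scale.
#' @param onset_delay_days Days after treatment entry before the effect
#'   begins.
#' @param ramp_days Days over which the effect accrues linearly.
#' @param effect_shape `"ramp"` (delayed gradual, the default) or
#'   `"step"`.
#' @param ar_coefficient Lag-1 autocorrelation of the latent noise, in
#'   \[0, 1).
#' @param noise_sd Innovation standard deviation of the latent noise.
#' @param missing_rate Probability a day's response is missing
#'   (missing completely at random), in \[0, 1).
#' @param seed Integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(baseline_level = 12,
                             effect_size = 10,
                             onset_delay_days = 21,
                             ramp_days = 35,
                             effect_shape = c("ramp", "step"),
                             ar_coefficient = 0.4,
                             noise_sd = 3,
                             missing_rate = 0.237,
                             seed = 1L) {
  effect_shape <- match.arg(effect_shape)
  if (baseline_level < 0 || baseline_level > 27) {
    stop_config("baseline_level must be on the 0-27 anxiety scale")
  }
  if (ar_coefficient < 0 || ar_coefficient >= 1) {
    stop_config("ar_coefficient must lie in [0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_config("missing_rate must lie in [0, 1)")
  }
  if (noise_sd < 0 || effect_size < 0 || onset_delay_days < 0 || ramp_days < 0) {
    stop_config("effect_size, onset_delay_days, ramp_days and noise_sd must be nonnegative")
  }
  structure(
    list(
      baseline_level = baseline_level, effect_size = effect_size,
      onset_delay_days = onset_delay_days, ramp_days = ramp_days,
      effect_shape = effect_shape, ar_coefficient = ar_coefficient,
      noise_sd = noise_sd, missing_rate = missing_rate, seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

# Expected latent level per day under a config and design.
effect_mean_path <- function(config, design) {
  onset <- design$baseline_days + config$onset_delay_days
  if (config$onset_delay_days + config$ramp_days >
      design$treatment_days + design$followup_days) {
    stop_config("effect onset + ramp exceed the post-baseline course")
  }
  t <- seq_len(design$total_days)
  if (config$effect_shape == "step" || config$ramp_days == 0) {
    drop <- ifelse(t <= onset, 0, config$effect_size)
  } else {
    drop <- pmin(pmax(t - onset, 0) / config$ramp_days, 1) * config$effect_size
  }
  config$baseline_level - drop
}

#' Simulate one daily outcome series
#'
#' @param config A [generator_config()].
#' @param design A [phase_design()].
#' @param bounds Length-2 numeric, the outcome's score range (default
#'   `c(0, 27)`, the daily anxiety sum).
#' @return Tibble with one row per day: `day_index`, `phase`, `latent`
#'   (the continuous process, never missing), `value` (rounded, clipped,
#'   `NA` on missing days), `missing`.
#' @export
#' @examples
#' s <- simulate_series(generator_config(seed = 7), phase_design(12))
#' range(s$value, na.rm = TRUE)
simulate_series <- function(config, design, bounds = c(0, 27)) {
  stopifnot(inherits(config, "generator_config"), inherits(design, "phase_design"))
  if (bounds[1] > bounds[2]) stop_config("inverted outcome bounds")
  mu <- effect_mean_path(config, design)
  n <- design$total_days
  with_seed_maybe(config$seed, {
    e <- numeric(n)
    stat_sd <- if (config$ar_coefficient > 0) {
      config$noise_sd / sqrt(1 - config$ar_coefficient^2)
    } else {
      config$noise_sd
    }
    e[1] <- rnorm(1, 0, stat_sd)
    if (n > 1) {
      z <- rnorm(n - 1, 0, config$noise_sd)
      for (t in 2:n) e[t] <- config$ar_coefficient * e[t - 1] + z[t - 1]
    }
    latent <- mu + e
    missing <- runif(n) < config$missing_rate
    value <- pmin(pmax(round(latent), bounds[1]), bounds[2])
    value[missing] <- NA_real_
    tibble(
      day_index = seq_len(n),
      phase = phase_labels(design),
      latent = latent,
      value = value,
      missing = missing
    )
  })
}

#' Simulate a replicated single-case cohort
#'
#' Designs are drawn by stratified randomization with cyclic stratum
#' allocation in enrollment order; per-participant seeds are derived
#' deterministically from `master_seed`. All three daily outcomes share
#' one latent anxiety process per participant, kept coherent: the
#' anxiety sum is the latent process rounded to 0-27, impact is the same
#' process rescaled to 0-9, and value-based action is its mirror
#' (9 minus the impact-scale value), so that less anxiety co-occurs with
#' less impact and more value-based action. The daily missingness mask
#' is shared across the three outcomes, as an unanswered message loses
#' all five items at once.
#'
#' @param n_participants Number of participants (default 4).
#' @param space A [design_space()].
#' @param config A [generator_config()], or a list of one per
#'   participant.
#' @param master_seed Integer master seed.
#' @return An object of class `sced_cohort`: list with `daily` (long
#'   scored tibble: `participant_id`, `day_index`, `phase`,
#'   `anxiety_sum`, `impact`, `value_action`), `designs` (sidecar
#'   tibble), `configs`, `master_seed`.
#' @export
#' @examples
#' co <- simulate_cohort(4, master_seed = 42)
#' dplyr::count(co$daily, participant_id)
simulate_cohort <- function(n_participants = 4,
                            space = design_space(),
                            config = generator_config(),
                            master_seed = 1L) {
  if (n_participants < 1) stop_config("n_participants must be at least 1")
  configs <- if (inherits(config, "generator_config")) {
    rep(list(config), n_participants)
  } else {
    stopifnot(length(config) == n_participants)
    config
  }
  strata <- withr::with_seed(master_seed, suppressWarnings(
    allocate_strata(n_participants, length(space$strata))
  ))
  seeds <- derive_seeds(master_seed, 2L * n_participants)
  daily <- vector("list", n_participants)
  designs <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    pid <- sprintf("P%d", i)
    design <- draw_design(space, strata[i], seed = seeds[2L * i - 1L])
    cfg <- configs[[i]]
    cfg$seed <- seeds[2L * i]
    s <- simulate_series(cfg, design, bounds = c(0, 27))
    impact9 <- pmin(pmax(round(s$latent * 9 / 27), 0), 9)
    impact9[s$missing] <- NA_real_
    daily[[i]] <- tibble(
      participant_id = pid,
      day_index = s$day_index,
      phase = s$phase,
      anxiety_sum = s$value,
      impact = impact9,
      value_action = 9 - impact9
    )
    designs[[i]] <- tibble(
      participant_id = pid,
      baseline_days = design$baseline_days,
      treatment_days = design$treatment_days,
      followup_days = design$followup_days,
      total_days = design$total_days,
      stratum = strata[i]
    )
  }
  structure(
    list(
      daily = dplyr::bind_rows(daily),
      designs = dplyr::bind_rows(designs),
      configs = configs,
      master_seed = as.integer(master_seed)
    ),
    class = "sced_cohort"
  )
}

#' @export
print.sced_cohort <- function(x, ...) {
  cat(sprintf(
    "<sced_cohort> %d participants x %d days (master seed %d)\n",
    nrow(x$designs), x$designs$total_days[1], x$master_seed
  ))
  invisible(x)
}

#' Rewrite a simulated cohort as raw daily responses
#'
#' Inverts the scoring so that the generator can emit the same raw CSV
#' dialect the study's data capture produced: the anxiety sum is split
#' as evenly as possible across items 1-3, items are shifted back to the
#' raw 1-10 scale, and missing days become unanswered rows (all items
#' `NA`). [score_daily()] applied to the result reproduces the cohort's
#' scores exactly.
#'
#' @param cohort An `sced_cohort`.
#' @return Tibble of raw daily responses.
#' @export
cohort_to_responses <- function(cohort) {
  d <- cohort$daily
  base <- d$anxiety_sum %/% 3
  rem <- d$anxiety_sum %% 3
  tibble(
    participant_id = d$participant_id,
    day_index = d$day_index,
    item1 = base + as.integer(rem >= 1) + 1L,
    item2 = base + as.integer(rem >= 2) + 1L,
    item3 = base + 1L,
    item4 = d$impact + 1L,
    item5 = d$value_action + 1L,
    same_day = TRUE
  )
}
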