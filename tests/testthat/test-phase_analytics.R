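test_that("phase summaries report level, variability and trend", {
  d <- small_design(4, 8, 16)
  v <- rep(NA_real_, 16)
  v[1:4] <- 5 # constant baseline
  s <- summarize_phase(v, d, "A")
  expect_equal(s$mean, 5); expect_equal(s$range, 0); expect_equal(s$trend_slope, 0)
  # exact unit slope
  v[5:8] <- c(0, 1, 2, 3)
  sB <- summarize_phase(v, d, "B")
  expect_equal(sB$trend_slope, 1.0)
  expect_equal(sB$n_observed, 4)
  # empty phase yields an "insufficient data" row, not an error
  sC <- summarize_phase(v, d, "C")
  expect_equal(sC$n_observed, 0)
  expect_equal(sC$note, "insufficient data")
  expect_true(is.na(sC$mean))
})

test_that("the OLS trend matches the closed-form least-squares oracle", {
  withr::with_seed(21, {
    for (rep in 1:25) {
      d <- small_design()
      v <- random_small_series(d)
      for (ph in c("A", "B", "C")) {
        lab <- phase_labels(d)
        idx <- which(lab == ph & !is.na(v))
        if (length(idx) < 2 || length(unique(idx)) < 2) next
        s <- summarize_phase(v, d, ph)
        expect_equal(s$trend_slope, oracle_ols_slope(idx, v[idx]), tolerance = 1e-10)
        expect_equal(s$min, min(v[idx])); expect_equal(s$max, max(v[idx]))
      }
    }
  })
})

test_that("split-middle trend recovers an exact line and differs from OLS under outliers", {
  d <- phase_design(20, 56, 96)
  v <- rep(NA_real_, 96); v[1:20] <- 2 * (1:20) + 3
  s <- summarize_phase(v, d, "A", trend_method = "split_middle")
  expect_equal(s$trend_slope, 2)
  expect_equal(s$trend_intercept, 3)
  # a gross outlier moves OLS but not the median-based line
  v[10] <- 300
  expect_equal(summarize_phase(v, d, "A", "split_middle")$trend_slope, 2,
               tolerance = 0.2)
  expect_gt(abs(summarize_phase(v, d, "A", "ols")$trend_slope - 2), 0.2)
})

test_that("level change is the later minus the earlier phase mean", {
  d <- small_design()
  v <- c(rep(10, 4), rep(7.6, 8), rep(7.6, 4))
  expect_equal(level_change(v, d, "A", "B"), -2.4)
  expect_equal(level_change(v, d, "B", "C"), 0)
  withr::with_seed(33, {
    for (rep in 1:25) {
      v <- random_small_series(d)
      lab <- phase_labels(d)
      a <- v[lab == "A"]; b <- v[lab == "B"]
      if (all(is.na(a)) || all(is.na(b))) next
      expect_equal(level_change(v, d, "A", "B"),
                   mean(b, na.rm = TRUE) - mean(a, na.rm = TRUE))
      # telescoping across the three phases
      cph <- v[lab == "C"]
      if (!all(is.na(cph))) {
        expect_equal(
          level_change(v, d, "A", "B") + level_change(v, d, "B", "C"),
          mean(cph, na.rm = TRUE) - mean(a, na.rm = TRUE),
          tolerance = 1e-10
        )
      }
    }
  })
})

test_that("POD hits 0% for a perfect effect and 100% for complete overlap", {
  d <- small_design()
  # all later points below the previous minimum (decrease is improvement)
  v <- c(rep(10:13, 1), rep(10, 0), rep(2, 12))
  p <- pod(v, d, "A", "B", direction = "decrease")
  expect_equal(p$pod_percent, 0)
  # all later points above the previous minimum
  v2 <- c(rep(5, 4), rep(9, 12))
  expect_equal(pod(v2, d, "A", "B", "decrease")$pod_percent, 100)
  # mirrored rule for increase-is-better outcomes
  v3 <- c(rep(5, 4), rep(9, 12))
  expect_equal(pod(v3, d, "A", "B", "increase")$pod_percent, 0)
  expect_equal(pod(c(rep(5, 4), rep(1, 12)), d, "A", "B", "increase")$pod_percent, 100)
})

test_that("POD tie handling follows the configured rule", {
  d <- small_design()
  v <- c(rep(5, 4), rep(5, 12)) # every later point ties the baseline minimum
  expect_equal(pod(v, d, "A", "B", "decrease", ties = "strict")$pod_percent, 0)
  expect_equal(pod(v, d, "A", "B", "decrease", ties = "overlap")$pod_percent, 100)
})

test_that("POD equals the brute-force pairwise count oracle and is monotone", {
  withr::with_seed(44, {
    for (rep in 1:50) {
      d <- small_design()
      v <- random_small_series(d)
      lab <- phase_labels(d)
      if (all(is.na(v[lab == "A"])) || all(is.na(v[lab == "B"]))) next
      p <- pod(v, d, "A", "B", "decrease")
      o <- oracle_pod_count(v, d, "A", "B", decrease = TRUE)
      expect_equal(p$n_overlapping, o$n_overlapping)
      expect_equal(p$n_later_observed, o$n_later)
      expect_equal(p$pod_percent, 100 * o$n_overlapping / o$n_later)
      expect_true(p$pod_percent >= 0 && p$pod_percent <= 100)
      # lowering every later point never increases POD
      v_low <- v; v_low[lab == "B"] <- v_low[lab == "B"] - 3
      expect_lte(pod(v_low, d, "A", "B", "decrease")$pod_percent, p$pod_percent)
    }
  })
})

test_that("immediacy contrasts the phase boundary and exposes delayed effects", {
  d <- phase_design(10, 56, 96)
  # step of -5 exactly at treatment entry
  v <- c(rep(10, 10), rep(5, 86))
  expect_equal(immediacy(v, d), -5)
  # constant no-effect series
  expect_equal(immediacy(rep(7, 96), d), 0)
  # delayed ramp: immediacy near zero while the full-phase change is negative
  cfg <- generator_config(baseline_level = 15, effect_size = 12,
                          onset_delay_days = 14, ramp_days = 28,
                          noise_sd = 0, missing_rate = 0, seed = 2)
  s <- simulate_series(cfg, d)
  expect_equal(immediacy(s$value, d), 0)
  expect_lt(level_change(s$value, d, "A", "B"), -1)
  # insufficient window
  sparse <- rep(NA_real_, 96); sparse[c(1, 11, 12, 13)] <- 5
  expect_true(is.na(immediacy(sparse, d)))
})

test_that("cohort analysis is per-participant and computed on observed values only", {
  co <- simulate_cohort(4, master_seed = 17)
  res <- analyze_cohort(co)
  expect_equal(nrow(res$changes), 4 * 3)
  expect_setequal(unique(res$changes$outcome),
                  c("anxiety_sum", "impact", "value_action"))
  # constant complete input: all changes 0, POD 100% under the strict tie rule
  const <- list(
    daily = tibble::tibble(
      participant_id = "P1", day_index = 1:96, phase = phase_labels(phase_design(12)),
      anxiety_sum = 5, impact = 2, value_action = 7
    ),
    designs = tibble::tibble(participant_id = "P1", baseline_days = 12,
                             treatment_days = 56, followup_days = 28,
                             total_days = 96, stratum = 2)
  )
  rc <- analyze_cohort(const)
  expect_true(all(rc$changes$change_a_b == 0))
  # under the literal "above the lowest value" rule ties never overlap,
  # so a flat series scores POD 0; the overlap tie rule scores it 100
  expect_true(all(rc$changes$pod_a_b == 0))
  rc2 <- analyze_cohort(const, ties = "overlap")
  expect_true(all(rc2$changes$pod_a_b == 100))
  # statistics are invariant to the values stored on missing days:
  # same observed data, different participant order
  co_perm <- co
  ord <- withr::with_seed(1, sample(nrow(co$daily)))
  co_perm$daily <- co$daily[ord, ]
  res_perm <- analyze_cohort(co_perm)
  expect_equal(dplyr::arrange(res_perm$changes, participant_id, outcome),
               dplyr::arrange(res$changes, participant_id, outcome))
})
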