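test_that("the mean-difference statistic contrasts baseline against the pooled later phases", {
  d <- phase_design(10)
  expect_equal(mean_diff_stat(c(rep(10, 10), rep(4, 86)), d), 6)
  expect_equal(mean_diff_stat(rep(3, 96), d), 0)
  withr::with_seed(11, {
    for (rep in 1:25) {
      v <- as.numeric(sample(0:27, 96, replace = TRUE))
      v[runif(96) < 0.2] <- NA
      expect_equal(mean_diff_stat(v, d), oracle_mean_diff(v, d))
    }
  })
  expect_error(mean_diff_stat(rep(1, 50), d), class = "scedrand_validation_error")
})

test_that("a uniquely most extreme statistic earns the smallest attainable p", {
  sp <- design_space()
  # high baseline for exactly the 7 shortest days, then floor: the statistic
  # is strictly decreasing in candidate baseline length
  v <- c(rep(20, 7), rep(0, 89))
  rt <- randomization_test(v, sp, phase_design(7))
  expect_equal(rt$p_value, 1 / 20)
  expect_equal(rt$n_scenarios, 20)
  expect_equal(rt$observed_stat, 20)
  expect_true(phase_design(7)$baseline_days %in% rt$null_stats$baseline_days)
})

test_that("complete ties give p = 1 and the attainable p values are k/20", {
  sp <- design_space()
  rt <- randomization_test(rep(5, 96), sp, phase_design(15))
  expect_equal(rt$p_value, 1)
  expect_true(all(rt$null_stats$stat == 0))
  withr::with_seed(13, {
    ps <- vapply(1:60, function(i) {
      v <- as.numeric(sample(0:27, 96, replace = TRUE))
      randomization_test(v, sp, phase_design(sample(7:26, 1)))$p_value
    }, numeric(1))
    expect_true(all(ps %in% ((1:20) / 20))) # granularity of the discrete null
    expect_true(all(ps >= 1 / 20))
  })
})

test_that("the randomization p matches an independent enumeration oracle", {
  sp <- design_space()
  withr::with_seed(17, {
    for (rep in 1:30) {
      v <- as.numeric(sample(0:27, 96, replace = TRUE))
      v[runif(96) < 0.25] <- NA
      b <- sample(7:26, 1)
      rt <- randomization_test(v, sp, phase_design(b))
      expect_equal(rt$p_value, oracle_randomization_p(v, sp, b))
    }
  })
})

test_that("sidedness and the stratum-restricted scenario set behave as declared", {
  v <- c(rep(20, 7), rep(0, 89))
  sp <- design_space()
  expect_equal(randomization_test(v, sp, phase_design(7), "less")$p_value, 1)
  expect_equal(randomization_test(v, sp, phase_design(7), "two.sided")$p_value, 1 / 20)
  rt_str <- randomization_test(v, sp, phase_design(7), scenario_set = "stratum")
  expect_equal(rt_str$n_scenarios, 5) # baselines 7..11
  expect_equal(rt_str$p_value, 1 / 5)
  expect_error(
    randomization_test(v, sp, phase_design(7, 56, 200)),
    class = "scedrand_config_error"
  )
})

test_that("scenarios with an empty observed side are dropped with a warning", {
  v <- rep(NA_real_, 96)
  v[8:96] <- 5 # baseline 7 has no observed value
  expect_warning(
    rt <- randomization_test(v, design_space(), phase_design(10)),
    "dropped"
  )
  expect_equal(rt$n_scenarios, 19)
})

test_that("Edgington combination follows the sum-of-uniforms distribution", {
  # the four per-participant p values from the replicated study
  e <- edgington_combine(c(0.45, 0.99, 0.35, 0.50))
  expect_equal(round(e$combined_p, 2), 0.69)
  # insensitive to reading the bounded entry as 1.00
  e2 <- edgington_combine(c(0.45, 1.00, 0.35, 0.50))
  expect_equal(round(e2$combined_p, 2), 0.69)
  # n = 1 identity and the exact two-uniform convolution
  expect_equal(edgington_combine(0.05)$combined_p, 0.05)
  expect_equal(edgington_combine(c(0.5, 0.5))$combined_p, 0.5)
  # monotone nondecreasing in each component
  expect_lte(edgington_combine(c(0.4, 0.99, 0.35, 0.50))$combined_p, e$combined_p)
  # validation
  expect_error(edgington_combine(numeric(0)), class = "scedrand_validation_error")
  expect_error(edgington_combine(c(0.5, 0)), class = "scedrand_validation_error")
  expect_error(edgington_combine(c(0.5, 1.2)), class = "scedrand_validation_error")
  # all-ones input stays capped at 1
  expect_equal(edgington_combine(rep(1, 4))$combined_p, 1)
})

test_that("Edgington matches a Monte-Carlo sum-of-uniforms estimate", {
  withr::with_seed(23, {
    for (rep in 1:5) {
      n <- sample(2:6, 1)
      p <- runif(n, 0.05, 1)
      s <- sum(p)
      draws <- matrix(runif(20000 * n), ncol = n)
      mc <- mean(rowSums(draws) <= s)
      se <- sqrt(mc * (1 - mc) / 20000)
      expect_lt(abs(edgington_combine(p)$combined_p - mc), max(3 * se, 1e-3))
    }
  })
})

test_that("Tau-U handles dominance, ties and the trend correction", {
  d <- small_design()
  # every post-entry value below every baseline value, flat baseline
  v <- c(rep(10, 4), rep(2, 12))
  t_corr <- tau_u(v, d)
  expect_equal(t_corr$s_cross, -4 * 12)
  expect_equal(t_corr$s_trend_a, 0)
  expect_equal(t_corr$tau_u, -48 / (48 + 6))
  t_unc <- tau_u(v, d, correct_baseline_trend = FALSE)
  expect_equal(t_unc$tau_u, -1)
  expect_equal(t_unc$variant, "uncorrected")
  # all ties
  expect_equal(tau_u(rep(5, 16), d)$tau_u, 0)
  # insufficient data
  short <- rep(NA_real_, 16); short[5:16] <- 3
  expect_equal(tau_u(short, d)$note, "insufficient data")
  expect_true(is.na(tau_u(short, d)$tau_u))
})

test_that("Tau-U pair counts equal the exhaustive oracle and are antisymmetric", {
  withr::with_seed(29, {
    for (rep in 1:50) {
      d <- small_design()
      v <- random_small_series(d)
      o <- oracle_tau_counts(v, d)
      if (o$n_a < 2 || o$n_bc < 1) next
      t <- tau_u(v, d)
      expect_equal(t$s_cross, o$s_cross)
      expect_equal(t$s_trend_a, o$s_trend_a)
      expect_equal(t$n_a, o$n_a); expect_equal(t$n_bc, o$n_bc)
      expect_lte(abs(t$tau_u), 1)
      # negating all values negates both pair counts
      t_neg <- tau_u(-v, d)
      expect_equal(t_neg$s_cross, -t$s_cross)
      expect_equal(t_neg$s_trend_a, -t$s_trend_a)
    }
  })
})

test_that("cohort inference assembles the report table with display rendering", {
  co <- simulate_cohort(4, master_seed = 31)
  res <- run_inference(co)
  expect_equal(nrow(res$table), 5)
  expect_equal(res$table$participant_id[5], "All combined")
  expect_equal(res$table$p_value[5], res$combined$combined_p)
  expect_true(all(res$table$n_scenarios[1:4] == 20))
  expect_equal(res$flags$tau_u_variant, "trend_corrected")
  # single participant: combined p equals that participant's p
  co1 <- simulate_cohort(1, master_seed = 31)
  r1 <- run_inference(co1)
  expect_equal(r1$combined$combined_p, r1$table$p_value[1])
  # a constant cohort renders p as the ">=.99" bound
  const <- list(
    daily = tibble::tibble(
      participant_id = "P1", day_index = 1:96,
      phase = phase_labels(phase_design(12)),
      anxiety_sum = 5, impact = 2, value_action = 7
    ),
    designs = tibble::tibble(participant_id = "P1", baseline_days = 12,
                             treatment_days = 56, followup_days = 28,
                             total_days = 96, stratum = 2)
  )
  rc <- run_inference(const)
  expect_equal(rc$table$p_display[1], ">=.99")
})

test_that("a strong immediate effect earns smaller p than a null effect", {
  strong <- generator_config(baseline_level = 15, effect_size = 10,
                             onset_delay_days = 0, ramp_days = 7, noise_sd = 2)
  null <- generator_config(baseline_level = 15, effect_size = 0, noise_sd = 2)
  p_of <- function(cfg, seeds) {
    vapply(seeds, function(s) {
      co <- simulate_cohort(1, config = cfg, master_seed = s)
      run_inference(co)$table$p_value[1]
    }, numeric(1))
  }
  p_strong <- p_of(strong, 1:60)
  p_null <- p_of(null, 1:60)
  expect_lt(median(p_strong), median(p_null))
  expect_gt(mean(p_strong == 0.05), mean(p_null == 0.05))
})
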