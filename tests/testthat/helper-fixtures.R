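# Shared fixtures and independent brute-force oracles.

`%||%` <- function(x, y) if (is.null(x)) y else x

# A small random day-indexed series with missingness, on a miniature course.
random_small_series <- function(design, prob_missing = 0.2) {
  v <- sample(0:27, design$total_days, replace = TRUE)
  v[runif(design$total_days) < prob_missing] <- NA
  as.numeric(v)
}

small_design <- function(baseline = 4L, treatment = 8L, total = 16L) {
  phase_design(baseline, treatment, total)
}

small_space <- function() {
  design_space(
    total_days = 16L, treatment_days = 8L, baseline_min = 3L, baseline_max = 6L,
    strata = list(c(3L, 4L), c(5L, 6L))
  )
}

# Oracle: mean difference by direct recomputation from phase labels.
oracle_mean_diff <- function(values, design) {
  lab <- phase_labels(design)
  mean(values[lab == "A"], na.rm = TRUE) - mean(values[lab != "A"], na.rm = TRUE)
}

# Oracle: one-sided randomization p by explicit enumeration.
oracle_randomization_p <- function(values, space, observed_baseline) {
  baselines <- seq(space$baseline_min, space$baseline_max)
  stats <- sapply(baselines, function(b) {
    a <- values[1:b]
    bc <- values[(b + 1):space$total_days]
    if (all(is.na(a)) || all(is.na(bc))) return(NA_real_)
    mean(a, na.rm = TRUE) - mean(bc, na.rm = TRUE)
  })
  obs <- stats[baselines == observed_baseline]
  stats <- stats[!is.na(stats)]
  sum(stats >= obs - 1e-12) / length(stats)
}

# Oracle: Tau-U pair counts by explicit double loops.
oracle_tau_counts <- function(values, design) {
  lab <- phase_labels(design)
  a <- values[lab == "A"]; a <- a[!is.na(a)]
  bc <- values[lab != "A"]; bc <- bc[!is.na(bc)]
  s_cross <- 0
  for (x in a) for (y in bc) s_cross <- s_cross + sign(y - x)
  s_trend <- 0
  if (length(a) >= 2) {
    for (i in seq_len(length(a) - 1)) {
      for (j in seq(i + 1, length(a))) s_trend <- s_trend + sign(a[j] - a[i])
    }
  }
  list(s_cross = s_cross, s_trend_a = s_trend,
       n_a = length(a), n_bc = length(bc))
}

# Oracle: POD overlap count by explicit loop (decrease-is-better).
oracle_pod_count <- function(values, design, from, to, decrease = TRUE) {
  lab <- phase_labels(design)
  f <- values[lab == from]; f <- f[!is.na(f)]
  t <- values[lab == to]; t <- t[!is.na(t)]
  n <- 0
  for (y in t) {
    hit <- if (decrease) y > min(f) else y < max(f)
    if (hit) n <- n + 1
  }
  list(n_overlapping = n, n_later = length(t))
}

# Oracle: closed-form simple-regression slope.
oracle_ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}
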