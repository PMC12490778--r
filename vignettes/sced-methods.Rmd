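---
title: "Methods: randomization inference and quantified visual analysis for replicated single-case designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: randomization inference and quantified visual analysis for replicated single-case designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scedrand)
```

## The design and its randomization

Each participant's course has a fixed total length (default 96 daily
measurement points) partitioned into baseline (A), treatment (B, fixed
at 56 days) and follow-up (C). The only randomized quantity is the
baseline length, admissible between 7 and 26 days; follow-up absorbs
the remainder (14–33 days), so all courses are equally long. Baseline
lengths are stratified into short (7–11), medium (12–19) and long
(20–26) strata, and participants are allocated to strata cyclically in
enrollment order — with n not divisible by three, exact balance is
impossible and the allocation warns.

Day indexing is 1-based; the intervention starts on the first day of
phase B; phase boundaries are closed. All of this is parameterized in
`design_space()` rather than hard-coded, because the granularity of the
randomization distribution (20 admissible entries ⇒ smallest p of .05)
is itself a design property worth exploring: more admissible entries
buy smaller attainable p values at the cost of longer possible waits
for treatment.

## Daily measures

Five items arrive daily by text message, answered 1–10 and recoded 0–9.
Items 1–3 are summed to the daily anxiety score (0–27); the sum is
missing whenever any of the three items is missing — partial sums are
never rescaled, and nothing is imputed anywhere in the package, because
the analyses are defined on valid responses only. Item 4 (impact) and
item 5 (value-based action) are kept as single 0–9 scores. Responses
answered on a later day than sent are invalid and wholly missing.

Item 5 is worded so that higher raw responses already mean more of the
desired behavior. We therefore store the recoded value unchanged and
carry the orientation as an analysis flag (`direction = "increase"` in
POD and related features); an arithmetic reversal (9 − x) is available
as a config option (`reverse_value_action`) for datasets coded the
other way. Orientation-only handling was chosen because outcome
trajectories that stabilize at the ceiling score of 9 for improved
cases are only interpretable if the stored scale is
higher-is-better.

## Quantified visual analysis

`summarize_phase()`, `level_change()`, `pod()` and `immediacy()`
quantify the features a structured visual analysis examines: the phase
mean (level), minimum/maximum/range (variability), a within-phase
trend line, the immediacy of change at the treatment boundary, and the
overlap between phases.

- **Trend.** Ordinary least squares of value on day index within phase
  is the default — it is reproducible and checkable against the
  closed-form slope. The traditional split-middle (median-based) line
  is available via `trend_method = "split_middle"`; the two differ
  visibly under outliers, and the package treats the choice as a
  reporting flag rather than a scientific claim.
- **POD ties.** POD counts later-phase points *above the previous
  phase's lowest value* (for decrease-is-better outcomes). Points
  exactly at the previous extreme are counted as *not* overlapping
  (`ties = "strict"`), the literal reading of "above". The consequence
  is that a perfectly flat, unchanged series scores POD 0 — the same
  value as a perfect effect — so POD must always be read alongside the
  level change; `ties = "overlap"` gives the alternative convention
  (flat series ⇒ 100). Each result records the rule used.
- **Immediacy** contrasts the mean of the last k observed baseline
  points against the first k observed treatment points (default k = 3).
  Under a delayed effect it stays near zero while the full-phase level
  change is substantial; that contrast is the quantitative signature of
  delay.
- Missing days are skipped in every feature, never interpolated.
- Display rounding follows reporting practice (one decimal for mean
  changes, whole percent for POD); full-precision values are retained.

The package deliberately stops at numbers: qualitative judgments
("effective" / "questionable") and cross-participant consistency remain
human interpretive acts, supported by side-by-side tabulation only.

## Randomization test

The test statistic is Mean(A) − Mean(B∪C); treatment and follow-up are
pooled because no new intervention is introduced at the B/C boundary.
The exact null distribution is the set of statistics obtained by
recomputing T under **every** admissible design on the same observed
series; p is the proportion of scenarios at least as extreme as the
observed one, with the observed scenario included.

Decisions that the source design left open, and how they were fixed:

- **Sidedness.** One-sided in the improvement direction by default
  (large Mean(A) − Mean(B∪C) ⇒ the outcome fell after entry). This
  matches the directional hypothesis and the arithmetic by which a
  uniquely most extreme statistic earns exactly 1/20; `"less"` and
  `"two.sided"` are provided. The choice is echoed in every output.
- **Scenario set.** The null enumerates all 20 admissible entries, not
  only the observed stratum — the natural reading of a scheme with "20
  possible treatment entries". A stratum-restricted mode exists for
  sensitivity analysis (it coarsens the attainable p values).
- **Ties** with the observed statistic count as "as or more extreme"
  (conservative; guarantees p ≥ 1/n).
- **Missing data.** Phase means use observed values only. A candidate
  scenario with no observed value on one side is dropped from the null
  set with a warning and n reduced — preferable to inventing a
  statistic for an uninformative scenario.

The test's validity needs no noise model: it comes from the design. The
acceptance-grade property test verifies on 2,000 simulated null cohorts
that P(p ≤ α) ≤ α within the binomial Monte-Carlo bound.

## Edgington additive combination

Replicated cases are combined by referring S = Σ pᵢ to the Irwin–Hall
CDF (sum of n independent uniforms). The alternating-sign closed form
is numerically safe for small n (here n = 4); the result is capped at 1
because the expression can exceed it only through floating error near
S = n. Inputs must lie in (0, 1] — a randomization p can never be 0.

## Tau-U

`tau_u()` counts sign(value_j − value_i) over all cross-phase pairs
(i in A, j in B∪C) and, when correcting for baseline trend, subtracts
the within-baseline ordered pair count, dividing by
n_A·n_BC + n_A(n_A−1)/2. Published Tau-U variants disagree about the
denominator; the trend-corrected form above is the default and the
plain nonoverlap τ = S_cross/(n_A·n_BC) is selectable, with the variant
always recorded in the result. Without raw data from any particular
study the variant cannot be adjudicated externally, which is exactly
why it is a recorded flag rather than a constant.

## The synthetic cohort generator

The generator's job is to produce data with the statistical structure
the analysis assumes — not to fit any particular published trajectory.
Per participant, a latent process x_t = μ_t + e_t with AR(1) noise
(e_t = φ e_{t−1} + σ z_t, stationary start) is rounded and clipped to
the outcome bounds; each day is missing completely at random at a flat
rate shared across the three outcomes (an unanswered message loses all
items at once). The mean path μ_t is flat through baseline and the
first `onset_delay_days` of treatment, then declines linearly by
`effect_size` over `ramp_days` (a step shape is available for
null/power contrast). Impact is the same latent process scaled to 0–9
and value-based action is its mirror, keeping the three outcomes
coherent within participant.

Defaults, chosen once as plausible for daily anxiety sums on a 0–27
scale: baseline level 12, effect size 10, onset delay 21 d and ramp
35 d (the effect completes by the end of the 56-day treatment phase,
i.e. improvement concentrates toward the end of treatment and
follow-up), φ = 0.4, innovation SD 3, missing rate 0.237. The missing
rate matches the observed proportion in the kind of study the package
targets; the autocorrelation and variance are not asserted as facts
about any dataset — they are exposed configuration, since only
qualitative descriptions ("considerable variability") are typically
published.

What the generator does *not* emulate: missingness that depends on the
outcome (MNAR), day-of-week or reactivity effects, integer response
styles (e.g. preference for 0/5/9), and between-outcome divergence
within a participant. Passing tests on synthetic cohorts therefore
demonstrate the *machinery* is correct (scoring, enumeration, exact
p values, pair counts), not that real daily anxiety data follow an
AR(1) ramp model.

A useful emergent behavior: under the default *delayed* effect, Tau-U
is strongly negative while the randomization p values stay large,
because late treatment entries produce almost the same mean contrast as
the true one. The mean-difference statistic simply has little power
against delayed effects at this granularity — a methodological point
the simulation makes vivid.

## Numerical choices and degenerate inputs

- Statistic comparisons in the p-value count use a 1e−12 absolute
  tolerance so that exact ties produced by integer data are counted as
  ties regardless of floating arithmetic.
- Empty phases yield explicit "insufficient data" rows rather than
  exceptions, so cohort reports always render.
- Trend lines need ≥ 2 observed points; the immediacy window needs k
  points on each side; Tau-U with trend correction needs n_A ≥ 2.
- Seeds: every stochastic entry point takes an explicit seed;
  per-participant streams are derived deterministically from a master
  seed; drawing with a seed never perturbs the caller's RNG state.

## Problem sizes used in the test suite

The property-style tests use 2,000 null cohorts for test validity, 500
random miniature series (16-day courses) for the Tau-U/POD brute-force
oracles, 10^5 draws for the Monte-Carlo check of the Irwin–Hall CDF, a
6,000-day latent series for autocorrelation recovery and about 20,000
simulated days for missing-rate recovery — sizes at which the binomial
and Monte-Carlo tolerances quoted in the tests are sharp enough to
catch sign and off-by-one errors while the whole suite stays fast.

## Known limitations

- Multiple-baseline-across-participants designs with simultaneity
  constraints are out of scope.
- No autocorrelation adjustment is applied to the test statistic; the
  randomization test does not need one for validity, but power under
  strong serial dependence is not characterized here.
- Other nonoverlap indices (NAP, PND, PEM) and multilevel/Bayesian SCED
  models are not implemented.
- With 20 admissible entries the attainable p values are multiples of
  .05; combined inference across replicated cases (Edgington) is the
  intended route to finer conclusions.
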