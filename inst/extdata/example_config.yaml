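# Example run configuration for the scedrand pipeline.
# Every key is optional; omitted keys fall back to package defaults.

design:
  total_days: 96        # fixed course length per participant
  treatment_days: 56    # 8-week treatment phase B
  baseline_min: 7       # shortest admissible baseline (phase A)
  baseline_max: 26      # longest admissible baseline
  strata:               # allocation strata over baseline lengths
    - [7, 11]
    - [12, 19]
    - [20, 26]

generator:
  baseline_level: 12    # expected daily anxiety sum in baseline (0-27)
  effect_size: 10       # expected total drop by the end of the ramp
  onset_delay_days: 21  # days after treatment entry before the effect starts
  ramp_days: 35         # days over which the effect accrues linearly
  effect_shape: ramp    # ramp (delayed gradual) or step
  ar_coefficient: 0.4   # lag-1 autocorrelation of the latent process
  noise_sd: 3.0         # innovation SD of the latent process
  missing_rate: 0.237   # daily MCAR missingness probability

analysis:
  direction: greater            # one-sided: MeanA - MeanBC large = improvement
  tie_rule: strict              # POD: points at the previous extreme do not overlap
  scenario_set: all             # randomization null over all admissible entries
  tau_u_trend_correction: true  # subtract baseline-trend pairs in Tau-U
  trend_method: ols             # ols or split_middle
  immediacy_window: 3           # points per side at the phase boundary
  reverse_value_action: false   # keep item 5 orientation, no 9-x reversal

n_participants: 4
seed: 20260927
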