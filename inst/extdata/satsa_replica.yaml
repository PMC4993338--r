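# Default analysis profile: simulated 318-pair twin cohort analysed with
# the standard ladder (intercept-only, one-slope, two-slope latent growth
# curve models with sex, then GRS-adjusted two-slope models), knot and
# centering age 69.3 years, 4-SD outlier exclusion.
seed: 20260101
k_sd: 4
centering_age: 69.3
grs_ladder: true
simulate:
  n_pairs: 318
  prop_mz: 0.3559322
  prop_female_pairs: 0.585
  baseline_age_mean: 68.9
  baseline_age_sd: 9.7
  min_age: 50
  occasion_gaps: [4.4, 2.6, 2.2, 2.2]
  retention: [1.0, 0.6886792, 0.6894977, 0.5430464, 0.3536585]
  fixed_effects:
    intercept: 0.7287
    slope1: -0.0012
    slope2: -0.0021
    sex_effect: -0.0409
    grs_effect: -0.011
  centering_age: 69.3
  residual_sd: 0.049
  plate_count: 20
  plate_effect_sd: 0.02
  duplicate_cv: 0.0698
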