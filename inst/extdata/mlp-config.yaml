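trial:
  n_intervention: 4618.0
  n_control: 4593.0
  entry_age_min: 45
  entry_age_max: 69
  followup_years: 10.0
  risk_factor_intervention: 1.0
  policy_intervention:
    interval: 0.3333333
    duration: 6.0
    attendance_prob: 0.75
  policy_control:
    interval: 1.0
    duration: 6.0
    attendance_prob: 0.0
  seed: 1
test:
  sens_II: 1.0
  sens_III: 1.0
  syserr_II: 0.0
  syserr_III: 0.0
  compound: no
natural_history:
  onset:
  - cell_type: squamous
    weibull_shape: 5.0
    weibull_mean: 62.0
    lifetime_onset_prob: 0.23
  - cell_type: adeno_large
    weibull_shape: 4.5
    weibull_mean: 61.0
    lifetime_onset_prob: 0.24
  - cell_type: small
    weibull_shape: 5.0
    weibull_mean: 60.0
    lifetime_onset_prob: 0.14
  progression:
  - cell_type: squamous
    mean_dwell_I: 1.2
    mean_dwell_II: 0.6
    mean_dwell_III: 0.4
    mean_dwell_IV: 0.4
    p_clinical_dx_at_III: 0.4
    indolent_fraction: 0.0
  - cell_type: adeno_large
    mean_dwell_I: 1.2
    mean_dwell_II: 0.5
    mean_dwell_III: 0.4
    mean_dwell_IV: 0.4
    p_clinical_dx_at_III: 0.4
    indolent_fraction: 0.0
  - cell_type: small
    mean_dwell_I: 0.7
    mean_dwell_II: 0.3
    mean_dwell_III: 0.25
    mean_dwell_IV: 0.25
    p_clinical_dx_at_III: 0.25
    indolent_fraction: 0.0
  mix:
    squamous: 0.35
    adeno_large: 0.45
    small: 0.2
life_table:
  kind: gompertz
  a: 0.0001
  b: 0.085
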