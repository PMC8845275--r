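# Oral semaglutide 14 mg versus dulaglutide 1.5 mg: network-meta-analysis
# comparison on the PIONEER 3 baseline cohort. The NMA reported changes in
# HbA1c, systolic blood pressure and BMI only; serum lipids, eGFR and
# hypoglycemia rates are set to zero so that unmodelled parameters cannot
# influence outcomes.
comparison: nma
cohort:
  label: "PIONEER 3 baseline"
  start_age: {mean: 57.86, sd: 9.87}
  duration: {mean: 9.00, sd: 5.98}
  proportion_male: 0.5282
  hba1c: {mean: 8.31, sd: 0.92}
  sbp: {mean: 133.83, sd: 15.41}
  bmi: {mean: 32.49, sd: 6.41}
  total_cholesterol: {mean: 180.0, sd: 40.0}
  hdl: {mean: 45.0, sd: 12.0}
  egfr: {mean: 90.0, sd: 20.0}
  proportion_smoker: 0.1417
  cigarettes_per_day: 13
  alcohol_oz_per_week: 7.97
arms:
  - arm_name: oral_semaglutide
    delta_hba1c: {mean: -1.50, se: 0.13}
    delta_sbp: {mean: -3.09, se: 1.13}
    delta_tc: {mean: 0.0, se: 0.0}
    delta_hdl: {mean: 0.0, se: 0.0}
    delta_bmi: {mean: -1.50, se: 0.18}
    delta_egfr: {mean: 0.0, se: 0.0}
    nonsevere_hypo_rate: 0.0
    severe_hypo_rate: 0.0
    nocturnal_fraction_nonsevere: 0.0
    nocturnal_fraction_severe: 0.0
  - arm_name: dulaglutide
    delta_hba1c: {mean: -1.29, se: 0.11}
    delta_sbp: {mean: -3.57, se: 1.08}
    delta_tc: {mean: 0.0, se: 0.0}
    delta_hdl: {mean: 0.0, se: 0.0}
    delta_bmi: {mean: -0.73, se: 0.17}
    delta_egfr: {mean: 0.0, se: 0.0}
    nonsevere_hypo_rate: 0.0
    severe_hypo_rate: 0.0
    nocturnal_fraction_nonsevere: 0.0
    nocturnal_fraction_severe: 0.0
simulation:
  horizon_years: 50
  discount_rate_costs: 0.04
  discount_rate_effects: 0.04
  n_patients: 10000
  seed: 20201
  switch_threshold_hba1c: 7.5
  intensification_policy: willis_linear
  hba1c_progression_law: ukpds_ar
  bmi_persistence: revert_on_switch
  risk_set: ukpds68
  basal_insulin_hypo_rates:
    nonsevere: 4.08
    severe: 0.10
    nocturnal_fraction_nonsevere: 0.25
    nocturnal_fraction_severe: 0.25
  utility_model_bmi: beaudet
  hypo_disutility_model: evans
  hba1c_ar:
    weight: 0.85
    attractor_intercept: 9.5
    attractor_slope: 0.0
  hba1c_linear_slope: 0.15
  willis:
    intercept: -1.20
    slope: 0.30
  target_hba1c: 7.0
  forced_switch_years: null
  secondary_drift:
    sbp_weight: 0.95
    sbp_attractor: 145.0
    tc_weight: 0.97
    tc_attractor: 200.0
    hdl_weight: 0.97
    hdl_attractor: 42.0
  death_accrual: half
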