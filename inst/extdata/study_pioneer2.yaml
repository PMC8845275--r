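# Oral semaglutide 14 mg versus empagliflozin 25 mg: head-to-head trial
# comparison. Baseline cohort and first-year treatment effects as published
# (trial-product estimand, 52 weeks); total/HDL cholesterol and eGFR
# baselines are defaults (not reported in the trial baseline table) and can
# be overridden here.
comparison: pioneer2
cohort:
  label: "PIONEER 2 baseline"
  start_age: {mean: 57.63, sd: 9.94}
  duration: {mean: 7.00, sd: 6.09}
  proportion_male: 0.5055
  hba1c: {mean: 8.14, sd: 0.94}
  sbp: {mean: 132.15, sd: 14.69}
  bmi: {mean: 32.82, sd: 6.11}
  total_cholesterol: {mean: 180.0, sd: 40.0}
  hdl: {mean: 45.0, sd: 12.0}
  egfr: {mean: 90.0, sd: 20.0}
  proportion_smoker: 0.1462
  cigarettes_per_day: 13
  alcohol_oz_per_week: 7.97
arms:
  - arm_name: oral_semaglutide
    delta_hba1c: {mean: -1.30, se: 0.05}
    delta_sbp: {mean: -4.85, se: 0.65}
    delta_tc: {mean: -5.08, se: 1.62}
    delta_hdl: {mean: 0.73, se: 0.35}
    delta_bmi: {mean: -1.73, se: 0.10}
    delta_egfr: {mean: 0.0, se: 0.0}
    nonsevere_hypo_rate: 2.25
    severe_hypo_rate: 0.25
    nocturnal_fraction_nonsevere: 0.11
    nocturnal_fraction_severe: 0.00
  - arm_name: empagliflozin
    delta_hba1c: {mean: -0.79, se: 0.05}
    delta_sbp: {mean: -4.34, se: 0.63}
    delta_tc: {mean: 4.74, se: 1.57}
    delta_hdl: {mean: 3.11, se: 0.34}
    delta_bmi: {mean: -1.37, se: 0.09}
    delta_egfr: {mean: 0.0, se: 0.0}
    nonsevere_hypo_rate: 1.90
    severe_hypo_rate: 0.24
    nocturnal_fraction_nonsevere: 0.13
    nocturnal_fraction_severe: 0.00
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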