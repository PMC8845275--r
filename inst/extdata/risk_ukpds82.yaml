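# Alternative risk-equation set (sensitivity analysis). Same schema and
# engine code path as the base-case catalog; only the coefficient data
# differ (generally lower baseline hazards and case fatalities, steeper
# age gradients, reflecting the later-era equation set's character).
label: ukpds82
events:
  mi:
    form: weibull_ph
    shape: 1.3
    intercept: -6.3
    coefficients:
      age_diag: 0.060
      male: 0.75
      smoker: 0.32
      hba1c: 0.13
      sbp: 0.011
      tc_hdl_ratio: 0.12
    centering:
      age_diag: 50
      hba1c: 7.0
      sbp: 135
      tc_hdl_ratio: 4.0
  stroke:
    form: weibull_ph
    shape: 1.55
    intercept: -8.2
    coefficients:
      age_diag: 0.070
      male: 0.35
      smoker: 0.32
      hba1c: 0.11
      sbp: 0.017
    centering:
      age_diag: 50
      hba1c: 7.0
      sbp: 135
  chf:
    form: weibull_ph
    shape: 1.5
    intercept: -8.6
    coefficients:
      age_diag: 0.095
      bmi: 0.075
      sbp: 0.012
      hba1c: 0.11
    centering:
      age_diag: 50
      bmi: 30
      sbp: 135
      hba1c: 7.0
  angina:
    form: weibull_ph
    shape: 1.3
    intercept: -7.3
    coefficients:
      age_diag: 0.062
      male: 0.28
      hba1c: 0.11
    centering:
      age_diag: 50
      hba1c: 7.0
  pvd:
    form: weibull_ph
    shape: 1.5
    intercept: -9.0
    coefficients:
      age_diag: 0.062
      smoker: 0.65
      hba1c: 0.15
      sbp: 0.008
    centering:
      age_diag: 50
      hba1c: 7.0
      sbp: 135
  renal_failure:
    form: weibull_ph
    shape: 1.8
    intercept: -10.8
    coefficients:
      hba1c: 0.16
      sbp: 0.013
      male: -0.18
    centering:
      hba1c: 7.0
      sbp: 135
  amputation:
    form: weibull_ph
    shape: 2.0
    intercept: -11.8
    coefficients:
      hba1c: 0.27
      smoker: 0.28
      pvd: 0.95
    centering:
      hba1c: 7.0
event_fatality:
  mi: 0.20
  stroke: 0.25
  amputation: 0.08
mortality:
  post_mi:
    condition: mi_history
    form: weibull_ph
    shape: 1.3
    intercept: -5.6
    coefficients:
      age: 0.045
    centering:
      age: 60
  post_stroke:
    condition: stroke_history
    form: weibull_ph
    shape: 1.3
    intercept: -5.4
    coefficients:
      age: 0.050
    centering:
      age: 60
  chf:
    condition: chf
    form: weibull_ph
    shape: 1.2
    intercept: -4.8
    coefficients:
      age: 0.032
    centering:
      age: 60
  esrd:
    condition: esrd
    form: constant_rate
    intercept: -2.30
  amputated:
    condition: amputated
    form: constant_rate
    intercept: -3.20
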