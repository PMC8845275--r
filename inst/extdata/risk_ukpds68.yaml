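# Base-case complication and mortality risk equations, in the UKPDS
# outcome-equation form: Weibull proportional hazards on diabetes duration
# with risk-factor covariates centred at reference values, plus
# constant-rate excess-mortality terms for end-stage states. The
# coefficient values shipped here are editable defaults in the published
# equations' functional form, not reproductions of any publication; they
# are the user-visible control surface of the risk engine.
label: ukpds68
events:
  mi:
    form: weibull_ph
    shape: 1.25
    intercept: -6.0
    coefficients:
      age_diag: 0.055
      male: 0.80
      smoker: 0.35
      hba1c: 0.12
      sbp: 0.010
      tc_hdl_ratio: 0.14
    centering:
      age_diag: 50
      hba1c: 7.0
      sbp: 135
      tc_hdl_ratio: 4.0
  stroke:
    form: weibull_ph
    shape: 1.5
    intercept: -8.0
    coefficients:
      age_diag: 0.066
      male: 0.40
      smoker: 0.35
      hba1c: 0.10
      sbp: 0.016
    centering:
      age_diag: 50
      hba1c: 7.0
      sbp: 135
  chf:
    form: weibull_ph
    shape: 1.5
    intercept: -8.4
    coefficients:
      age_diag: 0.090
      bmi: 0.070
      sbp: 0.012
      hba1c: 0.10
    centering:
      age_diag: 50
      bmi: 30
      sbp: 135
      hba1c: 7.0
  angina:
    form: weibull_ph
    shape: 1.3
    intercept: -7.0
    coefficients:
      age_diag: 0.060
      male: 0.30
      hba1c: 0.10
    centering:
      age_diag: 50
      hba1c: 7.0
  pvd:
    form: weibull_ph
    shape: 1.5
    intercept: -8.8
    coefficients:
      age_diag: 0.060
      smoker: 0.70
      hba1c: 0.14
      sbp: 0.008
    centering:
      age_diag: 50
      hba1c: 7.0
      sbp: 135
  renal_failure:
    form: weibull_ph
    shape: 1.8
    intercept: -10.5
    coefficients:
      hba1c: 0.15
      sbp: 0.013
      male: -0.20
    centering:
      hba1c: 7.0
      sbp: 135
  amputation:
    form: weibull_ph
    shape: 2.0
    intercept: -11.5
    coefficients:
      hba1c: 0.25
      smoker: 0.30
      pvd: 1.00
    centering:
      hba1c: 7.0
event_fatality:
  mi: 0.25
  stroke: 0.30
  amputation: 0.10
mortality:
  post_mi:
    condition: mi_history
    form: weibull_ph
    shape: 1.3
    intercept: -5.4
    coefficients:
      age: 0.040
    centering:
      age: 60
  post_stroke:
    condition: stroke_history
    form: weibull_ph
    shape: 1.3
    intercept: -5.2
    coefficients:
      age: 0.045
    centering:
      age: 60
  chf:
    condition: chf
    form: weibull_ph
    shape: 1.2
    intercept: -4.6
    coefficients:
      age: 0.030
    centering:
      age: 60
  esrd:
    condition: esrd
    form: constant_rate
    intercept: -2.12
  amputated:
    condition: amputated
    form: constant_rate
    intercept: -3.00
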