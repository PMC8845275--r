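test_that("first-year effects add the published deltas to the baseline", {
  p2 <- load_study_config("pioneer2")
  pt <- patient_row(hba1c = 8.14)
  out <- apply_first_year_effects(pt, p2$arms$oral_semaglutide)
  expect_equal(out$hba1c, 6.84)

  nma <- load_study_config("nma")
  pt3 <- patient_row(bmi = 32.49)
  out3 <- apply_first_year_effects(pt3, nma$arms$oral_semaglutide)
  expect_equal(out3$bmi, 30.99)

  # an all-zero profile is the identity
  idp <- effect_profile("nothing")
  same <- apply_first_year_effects(pt, idp)
  expect_equal(same$hba1c, pt$hba1c)
  expect_equal(same$bmi, pt$bmi)
  expect_equal(same$sbp, pt$sbp)
})

test_that("HbA1c progression laws behave as specified", {
  # linear with zero slope: constant
  flat <- progression_law("linear", slope = 0)
  pt <- patient_row(hba1c = 7.2)
  expect_equal(progress_hba1c(pt, flat)$hba1c, 7.2)

  # autoregressive law: the attractor is a fixed point
  law <- progression_law("ukpds_ar",
    weight = 0.85,
    attractor_intercept = 9.5, attractor_slope = 0
  )
  at <- patient_row(hba1c = 9.5)
  expect_equal(progress_hba1c(at, law)$hba1c, 9.5)

  # strictly increasing when below the attractor
  below <- patient_row(hba1c = 7)
  expect_gt(progress_hba1c(below, law)$hba1c, 7)

  # never negative
  neg <- progression_law("linear", slope = -10)
  expect_gte(progress_hba1c(patient_row(hba1c = 2), neg)$hba1c, 0)
})

test_that("between-arm HbA1c gaps contract under a shared autoregressive law", {
  law <- progression_law("ukpds_ar",
    weight = 0.85,
    attractor_intercept = 9.5, attractor_slope = 0
  )
  a <- patient_row(hba1c = 6.84)
  b <- patient_row(hba1c = 7.35)
  for (i in 1:4) { # cycles 2..5
    a <- progress_hba1c(a, law)
    b <- progress_hba1c(b, law)
  }
  gap5 <- b$hba1c - a$hba1c
  expect_lt(gap5, 0.51)
  # closed-form contraction of the linear recursion: gap * w^4
  expect_equal(gap5, 0.51 * 0.85^4, tolerance = 1e-12)
})

test_that("intensification responses follow the configured policy", {
  none <- intensification_policy("none")
  pt <- patient_row(hba1c = 8.2, bmi = 29, baseline_bmi = 30)
  out <- apply_intensification(pt, none)
  expect_equal(out$hba1c, 8.2)
  expect_equal(out$therapy, "basal_insulin")
  expect_equal(out$years_on_therapy, 0)
  expect_equal(out$bmi, 30) # reverted under the default persistence

  tgt <- intensification_policy("target_value", target = 7.0)
  out2 <- apply_intensification(patient_row(hba1c = 7.6), tgt)
  expect_equal(out2$hba1c, 7.0)

  # degenerate linear-response coefficients: drop floored at zero
  w0 <- intensification_policy("willis_linear", intercept = 0, slope = 0)
  out3 <- apply_intensification(patient_row(hba1c = 8.2), w0)
  expect_equal(out3$hba1c, 8.2)

  # the linear response never increases HbA1c
  wneg <- intensification_policy("willis_linear", intercept = -100, slope = 0)
  out4 <- apply_intensification(patient_row(hba1c = 8.2), wneg)
  expect_equal(out4$hba1c, 8.2)

  # maintain_lifetime keeps the treated BMI through the switch
  out5 <- apply_intensification(pt, none, bmi_persistence = "maintain_lifetime")
  expect_equal(out5$bmi, 29)
})

test_that("secondary risk factors drift autoregressively and never go negative", {
  cfg0 <- sim_config(secondary_drift = c(
    sbp_weight = 1, sbp_attractor = 145,
    tc_weight = 1, tc_attractor = 200,
    hdl_weight = 1, hdl_attractor = 42
  ))
  pt <- patient_row()
  out <- progress_secondary_factors(pt, cfg0)
  expect_equal(out$sbp, pt$sbp)
  expect_equal(out$tc, pt$tc)
  expect_equal(out$hdl, pt$hdl)

  cfg <- sim_config()
  out2 <- progress_secondary_factors(patient_row(sbp = 120), cfg)
  expect_gt(out2$sbp, 120) # below the attractor, drifts upward
  expect_lt(out2$sbp, 145)
  out3 <- progress_secondary_factors(patient_row(hdl = 1), cfg)
  expect_gte(out3$hdl, 0)
})

test_that("BMI trajectory is piecewise constant: baseline, treated, reverted", {
  # deterministic patient who must switch at the end of cycle 2
  study <- make_test_study(hba1c = 8.6, delta_a = -1.0, horizon = 8)
  pt <- sample_cohort(study$cohort, 1, seed = 1)
  trace <- simulate_patient(pt, study$arms$arm_a, study$config,
    catalogs = inert_catalogs(), seed = 2
  )
  # cycle 1: effects applied, 8.6 - 1.0 = 7.6 > 7.5 triggers the switch
  expect_equal(trace$hba1c[1], 7.6)
  expect_equal(trace$therapy, c("initial", rep("basal_insulin", 7)))
  expect_equal(trace$bmi[1], pt$bmi - 1.5)
  expect_equal(trace$bmi[-1], rep(pt$bmi, 7))

  # under lifetime persistence the treated BMI survives the switch
  study2 <- study
  study2$config$bmi_persistence <- "maintain_lifetime"
  trace2 <- simulate_patient(pt, study2$arms$arm_a, study2$config,
    catalogs = inert_catalogs(), seed = 2
  )
  expect_equal(trace2$bmi, rep(pt$bmi - 1.5, 8))
})

test_that("mean cohort HbA1c never decreases within a therapy phase", {
  study <- make_test_study(hba1c = 8.3, delta_a = -1.3, horizon = 15)
  pt <- sample_cohort(study$cohort, 1, seed = 1)
  trace <- simulate_patient(pt, study$arms$arm_a, study$config,
    catalogs = inert_catalogs(), seed = 2
  )
  # within each therapy phase the trajectory is non-decreasing from cycle 2
  for (phase in split(trace, trace$therapy)) {
    h <- phase$hba1c[phase$cycle >= 2]
    if (length(h) > 1) expect_true(all(diff(h) >= -1e-12))
  }
})

test_that("the empagliflozin arm intensifies earlier than oral semaglutide", {
  p2 <- load_study_config("pioneer2")
  a <- run_arm(p2, "oral_semaglutide", n_patients = 1500, seed = 21)
  b <- run_arm(p2, "empagliflozin", n_patients = 1500, seed = 21, comparator = TRUE)
  expect_lt(
    b$mean_years_on_initial_therapy,
    a$mean_years_on_initial_therapy
  )
})
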