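test_that("the acceptability curve equals its net-benefit definition", {
  scatter <- tibble::tibble(
    delta_qaly = c(0.1, 0.2, 0.05, 0.3),
    delta_cost = c(-100, 4000, 2000, 9000)
  )
  ceac <- ceac_curve(scatter, wtp = c(0, 20000, 40000, 1e6))
  # at zero willingness to pay: the fraction of cost-saving iterations
  expect_equal(ceac$probability_cost_effective[1], mean(scatter$delta_cost < 0))
  # manual oracle at 20k
  expect_equal(
    ceac$probability_cost_effective[2],
    mean(20000 * scatter$delta_qaly - scatter$delta_cost > 0)
  )
  # non-decreasing in WTP when every iteration has non-negative QALY gain
  expect_true(all(diff(ceac$probability_cost_effective) >= 0))
  expect_true(all(ceac$probability_cost_effective >= 0 &
    ceac$probability_cost_effective <= 1))
})

test_that("a degenerate PSA collapses onto the deterministic comparison", {
  study <- make_test_study(horizon = 8)
  for (arm in names(study$arms)) {
    for (f in t2dsim:::PROFILE_DELTA_FIELDS) study$arms[[arm]][[f]]$se <- 0
  }
  psa <- run_psa(study,
    n_iterations = 2, n_patients = 40, seed = 100,
    cost_cv = 0, utility_sd_frac = 0
  )
  det1 <- run_comparison(study, n_patients = 40, seed = 101)
  expect_equal(psa$scatter$delta_qaly[1], det1$ce$delta_qaly, tolerance = 1e-12)
  expect_equal(psa$scatter$delta_cost[1], det1$ce$delta_cost, tolerance = 1e-12)
  expect_equal(nrow(psa$scatter), 2)
  expect_s3_class(psa, "ce_result")
  expect_true(all(psa$ceac$probability_cost_effective >= 0 &
    psa$ceac$probability_cost_effective <= 1))
})

test_that("second-order sampling varies parameters between iterations", {
  study <- make_test_study(horizon = 6)
  psa <- run_psa(study, n_iterations = 4, n_patients = 30, seed = 55)
  expect_equal(nrow(psa$scatter), 4)
  expect_gt(length(unique(psa$scatter$delta_qaly)), 1)
})

test_that("the scenario suite covers every sensitivity-analysis row", {
  defs <- scenario_definitions()
  required <- c(
    "Base case",
    "Statistically significant differences only",
    "35-year time horizon", "20-year time horizon", "10-year time horizon",
    "0% discount rates", "3% discount rates",
    "BMI treatment effects maintained for patient lifetimes",
    "UKPDS HbA1c progression with no changes on treatment switch",
    "Upper 95% CI of HbA1c estimated treatment difference",
    "Lower 95% CI of HbA1c estimated treatment difference",
    "Upper 95% CI of BMI estimated treatment difference",
    "Lower 95% CI of BMI estimated treatment difference",
    "Treatment switching at 3 years with linear HbA1c progression",
    "Costs of complications +10%", "Costs of complications -10%",
    "UKPDS 82 risk equations applied",
    "Lee et al. BMI disutility applied",
    "Lauridsen et al. diminishing hypoglycemia model applied",
    "Currie et al. hypoglycemia disutilities applied",
    "Comparator price reduced by 10%"
  )
  expect_setequal(defs$label, required)

  tab <- run_scenario_suite(load_study_config("pioneer2"),
    n_patients = 120, seed = 14
  )
  expect_equal(nrow(tab), nrow(defs))
  expect_setequal(tab$scenario, defs$scenario)
  expect_true(all(is.finite(tab$delta_qaly)))
  expect_true(all(is.finite(tab$delta_cost)))

  expect_error(
    run_scenario_suite(load_study_config("pioneer2"), scenarios = "warp_drive"),
    "warp_drive",
    class = "t2dsim_argument_error"
  )
})

test_that("scenario transforms modify exactly the intended knobs", {
  study <- load_study_config("pioneer2")
  cats <- default_catalogs(study$config)
  tr <- t2dsim:::scenario_transforms()

  d0 <- tr$discount_0(study, cats)
  expect_equal(d0$study$config$discount_rate_costs, 0)
  expect_equal(d0$study$config$discount_rate_effects, 0)
  expect_equal(d0$study$arms, study$arms)

  bl <- tr$bmi_lifetime(study, cats)
  expect_equal(bl$study$config$bmi_persistence, "maintain_lifetime")

  ns <- tr$no_change_on_switch(study, cats)
  expect_equal(ns$study$config$intensification_policy, "none")

  # upper CI: the between-arm HbA1c difference widens by 1.96 pooled SEs
  up <- tr$hba1c_upper_ci(study, cats)
  diff0 <- study$arms[[1]]$delta_hba1c$mean - study$arms[[2]]$delta_hba1c$mean
  diff1 <- up$study$arms[[1]]$delta_hba1c$mean - up$study$arms[[2]]$delta_hba1c$mean
  pooled <- sqrt(study$arms[[1]]$delta_hba1c$se^2 + study$arms[[2]]$delta_hba1c$se^2)
  expect_equal(diff1, diff0 - 1.96 * pooled, tolerance = 1e-12)
  lo <- tr$hba1c_lower_ci(study, cats)
  diff2 <- lo$study$arms[[1]]$delta_hba1c$mean - lo$study$arms[[2]]$delta_hba1c$mean
  expect_equal(diff2, diff0 + 1.96 * pooled, tolerance = 1e-12)

  cp <- tr$costs_plus10(study, cats)
  expect_equal(cp$catalogs$costs$event_costs, cats$costs$event_costs * 1.1)
  expect_equal(cp$catalogs$costs$therapy_daily_cost, cats$costs$therapy_daily_cost)

  # significant-only: non-significant trial effects equalized across arms
  ss <- tr$stat_sig_only(study, cats)
  expect_equal(ss$study$arms[[1]]$delta_sbp, ss$study$arms[[2]]$delta_sbp)
  expect_equal(ss$study$arms[[1]]$nonsevere_hypo_rate, ss$study$arms[[2]]$nonsevere_hypo_rate)
  expect_equal(ss$study$arms[[1]]$delta_hba1c, study$arms[[1]]$delta_hba1c)
  expect_equal(ss$study$arms[[1]]$delta_bmi, study$arms[[1]]$delta_bmi)

  u82 <- tr$ukpds82(study, cats)
  expect_equal(u82$catalogs$risk$label, "ukpds82")

  pm <- tr$comparator_price_minus10(study, cats)
  expect_equal(pm$catalogs$costs$comparator_price_multiplier, 0.9)
})

test_that("key-driver runs isolate one parameter group at a time", {
  study <- load_study_config("pioneer2")
  kd <- run_key_drivers(study, n_patients = 60, seed = 3, drivers = c("hba1c", "bmi"))
  expect_equal(kd$driver, c("hba1c", "bmi"))
  expect_true(all(is.finite(kd$delta_qaly)))
  # NMA defaults to its three reported outcomes
  kd_nma <- run_key_drivers(load_study_config("nma"),
    n_patients = 40, seed = 3,
    drivers = "sbp"
  )
  expect_equal(nrow(kd_nma), 1)
  expect_error(
    run_key_drivers(study, drivers = "fairydust"),
    "fairydust",
    class = "t2dsim_argument_error"
  )
})
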