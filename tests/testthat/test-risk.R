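test_that("Weibull annual probability matches hand-evaluated cumulative hazards", {
  # constant hazard (shape 1): 1 - exp(-exp(L)) at any duration
  eq1 <- risk_equation("ev", "weibull_ph", intercept = log(0.02), shape = 1)
  for (dur in c(0, 3, 10)) {
    p <- annual_event_probability(patient_row(duration = dur), eq1)
    expect_equal(p, 1 - exp(-0.02), tolerance = 1e-12)
  }
  # shape 2, exp(L) = 0.001, t = 10: H(11) - H(10) = 0.001 * (121 - 100)
  eq2 <- risk_equation("ev", "weibull_ph", intercept = log(0.001), shape = 2)
  p <- annual_event_probability(patient_row(duration = 10), eq2)
  expect_equal(p, 1 - exp(-0.021), tolerance = 1e-12)
  # independent oracle: numerical integration of the hazard
  # h(t) = exp(L) * shape * t^(shape - 1)
  H <- integrate(function(t) 0.001 * 2 * t, 10, 11)$value
  expect_equal(p, 1 - exp(-H), tolerance = 1e-8)
})

test_that("Weibull with shape 1 equals the constant-rate form", {
  coef <- c(hba1c = 0.12, male = 0.5)
  cent <- c(hba1c = 7)
  w <- risk_equation("ev", "weibull_ph",
    intercept = -4, shape = 1,
    coefficients = coef, centering = cent
  )
  cr <- risk_equation("ev", "constant_rate",
    intercept = -4,
    coefficients = coef, centering = cent
  )
  pts <- dplyr::bind_rows(lapply(c(6, 7.5, 9, 11), function(h) patient_row(hba1c = h)))
  expect_equal(
    annual_event_probability(pts, w),
    annual_event_probability(pts, cr),
    tolerance = 1e-12
  )
})

test_that("probabilities rise monotonically in HbA1c under a positive coefficient", {
  eq <- risk_equation("ev", "weibull_ph",
    intercept = -5, shape = 1.3,
    coefficients = c(hba1c = 0.15), centering = c(hba1c = 7)
  )
  grid <- seq(4, 15, by = 0.5)
  pts <- dplyr::bind_rows(lapply(grid, function(h) patient_row(hba1c = h)))
  p <- annual_event_probability(pts, eq)
  expect_true(all(diff(p) > 0))
})

test_that("probabilities stay in [0,1] over randomized states and equations", {
  set.seed(42)
  for (i in 1:30) {
    eq <- risk_equation("ev",
      form = sample(c("weibull_ph", "logistic", "constant_rate"), 1),
      intercept = runif(1, -12, 2),
      shape = runif(1, 0.5, 3),
      coefficients = c(hba1c = runif(1, -0.3, 0.5), sbp = runif(1, -0.05, 0.05)),
      centering = c(hba1c = 7, sbp = 135)
    )
    pts <- patient_row(
      hba1c = runif(1, 4, 15), sbp = runif(1, 80, 220),
      duration = runif(1, 0, 50)
    )
    p <- annual_event_probability(pts, eq)
    expect_true(p >= 0 && p <= 1)
  }
  # degenerate intercept: probability exactly 0
  eq0 <- risk_equation("ev", "weibull_ph", intercept = -Inf, shape = 1.5)
  expect_equal(annual_event_probability(patient_row(), eq0), 0)
})

test_that("missing or unknown covariates raise configuration errors naming the tag", {
  eq <- risk_equation("ev", "logistic", coefficients = c(widget = 1))
  expect_error(
    annual_event_probability(patient_row(), eq),
    "widget",
    class = "t2dsim_config_error"
  )
})

test_that("death probability combines independent hazard sources", {
  # q_b = 0.01 with one event of fatality 0.2: 1 - 0.99 * 0.8 = 0.208
  p <- patient_row(age = 60)
  p$events <- list("mi")
  q <- annual_death_probability(p, flat_life_table(0.01),
    fatality = c(mi = 0.2)
  )
  expect_equal(q, 0.208, tolerance = 1e-12)
  # no hazard sources at all
  q0 <- annual_death_probability(patient_row(), zero_life_table())
  expect_equal(q0, 0)
  # age at or beyond the last band: certain death
  q1 <- annual_death_probability(patient_row(age = 250), zero_life_table(200))
  expect_equal(q1, 1)
  # age below the table start is a configuration error
  expect_error(
    annual_death_probability(patient_row(age = 10), zero_life_table()),
    class = "t2dsim_config_error"
  )
})

test_that("conditional excess-mortality equations apply only when their condition holds", {
  excess <- risk_equation("post_mi", "constant_rate",
    intercept = log(0.05),
    condition = "mi_history"
  )
  healthy <- patient_row()
  survivor <- patient_row(mi_history = TRUE)
  expect_equal(
    annual_death_probability(healthy, zero_life_table(), mortality_eqs = list(excess)),
    0
  )
  expect_equal(
    annual_death_probability(survivor, zero_life_table(), mortality_eqs = list(excess)),
    1 - exp(-0.05),
    tolerance = 1e-12
  )
})

test_that("cycle event sampling honors forced and degenerate probabilities", {
  pts <- patient_row()
  # all probabilities zero: state unchanged apart from bookkeeping columns
  out <- sample_cycle_events(pts, empty_risk_catalog(), zero_transitions())
  expect_equal(out$foot_stage, "none")
  expect_equal(out$retinopathy_stage, "none")
  expect_false(out$mi_history)
  expect_equal(out$events[[1]], character())
  expect_equal(out$hypo_ns_day + out$hypo_ns_noct, 0)

  # amputation probability 1: foot stage jumps to amputated with the tag
  certain_amp <- empty_risk_catalog()
  certain_amp$events$amputation <- risk_equation("amputation", "logistic", intercept = Inf)
  out2 <- sample_cycle_events(pts, certain_amp, zero_transitions())
  expect_equal(out2$foot_stage, "amputated")
  expect_true("amputation" %in% out2$events[[1]])

  # dead patients never accrue events
  dead <- patient_row(alive = FALSE)
  out3 <- sample_cycle_events(dead, certain_amp, zero_transitions(),
    nonsevere_rate = 5, severe_rate = 1
  )
  expect_equal(out3$foot_stage, "none")
  expect_equal(out3$events[[1]], character())
  expect_equal(out3$hypo_ns_day + out3$hypo_ns_noct, 0)
})

test_that("cohort incidence matches the per-patient probability (Monte Carlo oracle)", {
  p_true <- 0.3
  eq <- risk_equation("mi", "logistic", intercept = qlogis(p_true))
  cat <- empty_risk_catalog()
  cat$events$mi <- eq
  n <- 5000
  pts <- patient_row()[rep(1, n), ]
  pts$id <- seq_len(n)
  set.seed(7)
  out <- sample_cycle_events(pts, cat, zero_transitions())
  inc <- mean(out$mi_history)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(inc - p_true), 4 * se)
})

test_that("Poisson hypoglycemia sampling recovers the configured rates", {
  n <- 10000
  pts <- patient_row()[rep(1, n), ]
  pts$id <- seq_len(n)
  set.seed(11)
  out <- sample_cycle_events(pts, empty_risk_catalog(), zero_transitions(),
    nonsevere_rate = 4.08, severe_rate = 0.10,
    nocturnal_fraction_nonsevere = 0.25, nocturnal_fraction_severe = 0.25
  )
  ns <- out$hypo_ns_day + out$hypo_ns_noct
  sev <- out$hypo_sev_day + out$hypo_sev_noct
  expect_lt(abs(mean(ns) - 4.08) / 4.08, 0.02)
  expect_lt(abs(mean(sev) - 0.10) / 0.10, 0.10)
  expect_lt(abs(mean(out$hypo_ns_noct) / mean(ns) - 0.25), 0.02)
})

test_that("swapping risk catalogs changes outputs only through coefficients", {
  study <- make_test_study(horizon = 5)
  cat68 <- default_catalogs(study$config)
  relabelled <- cat68
  relabelled$risk$label <- "ukpds82-pretender"
  a <- run_arm(study, "arm_a", catalogs = cat68, n_patients = 30, seed = 4)
  b <- run_arm(study, "arm_a", catalogs = relabelled, n_patients = 30, seed = 4)
  expect_identical(a$per_patient, b$per_patient)

  # different coefficient data feed the same code path but shift the hazards
  r68 <- default_risk_coefficients("ukpds68")
  r82 <- default_risk_coefficients("ukpds82")
  pts <- patient_row(hba1c = 9)
  expect_false(isTRUE(all.equal(
    annual_event_probability(pts, r68$events$mi),
    annual_event_probability(pts, r82$events$mi)
  )))
})

test_that("stage chains only advance forward", {
  tabs <- default_transition_tables()
  full <- lapply(tabs, function(tt) {
    tt$p[] <- 1
    tt
  })
  pts <- patient_row()
  stages_n <- match("none", t2dsim:::NEPHROPATHY_STAGES)
  for (i in 1:8) {
    before_n <- match(pts$nephropathy_stage, t2dsim:::NEPHROPATHY_STAGES)
    before_r <- match(pts$retinopathy_stage, t2dsim:::RETINOPATHY_STAGES)
    pts <- sample_cycle_events(pts, empty_risk_catalog(), full)
    after_n <- match(pts$nephropathy_stage, t2dsim:::NEPHROPATHY_STAGES)
    after_r <- match(pts$retinopathy_stage, t2dsim:::RETINOPATHY_STAGES)
    expect_gte(after_n, before_n)
    expect_gte(after_r, before_r)
    expect_lte(after_n - before_n, 1)
  }
  # chains saturate at their terminal stages
  expect_equal(pts$nephropathy_stage, "esrd_transplant")
  expect_equal(pts$retinopathy_stage, "svl")
})
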