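test_that("forced survival over the horizon accrues exactly horizon life-years", {
  study <- make_test_study(hba1c = 6.5, delta_a = 0, horizon = 50)
  pt <- sample_cohort(study$cohort, 1, seed = 1)
  trace <- simulate_patient(pt, study$arms$arm_a, study$config,
    catalogs = inert_catalogs(), seed = 2
  )
  expect_equal(nrow(trace), 50)
  expect_equal(sum(trace$life_fraction), 50)
  expect_true(all(trace$alive_at_end))
})

test_that("traces are bitwise-identical under the same seed", {
  study <- make_test_study(horizon = 15)
  cats <- default_catalogs(study$config)
  pt <- sample_cohort(study$cohort, 1, seed = 1)
  t1 <- simulate_patient(pt, study$arms$arm_a, study$config, cats, seed = 33)
  t2 <- simulate_patient(pt, study$arms$arm_a, study$config, cats, seed = 33)
  expect_identical(t1, t2)
  t3 <- simulate_patient(pt, study$arms$arm_a, study$config, cats, seed = 34)
  expect_false(identical(t1, t3))
})

test_that("death in cycle one accrues half a cycle under the half-cycle convention", {
  study <- make_test_study(horizon = 10)
  cats <- inert_catalogs()
  cats$life_table <- certain_death_life_table()
  pt <- sample_cohort(study$cohort, 1, seed = 1)
  trace <- simulate_patient(pt, study$arms$arm_a, study$config, cats, seed = 2)
  expect_equal(trace$life_fraction[1], 0.5)
  expect_equal(sum(trace$life_fraction), 0.5)
  expect_false(any(trace$alive_at_end))

  # switchable to full-cycle accrual
  study2 <- study
  study2$config$death_accrual <- "full"
  trace2 <- simulate_patient(pt, study2$arms$arm_a, study2$config, cats, seed = 2)
  expect_equal(trace2$life_fraction[1], 1)
  expect_equal(sum(trace2$life_fraction), 1)
})

test_that("identical profiles under common random numbers give exact zero deltas", {
  study <- make_test_study(horizon = 10)
  study$arms$arm_b <- study$arms$arm_a
  study$arms$arm_b$arm_name <- "arm_b"
  study$arms$arm_b$annual_therapy_cost_key <- "oral_semaglutide"
  rc <- run_comparison(study, n_patients = 200, seed = 12)
  expect_identical(
    rc$arms[[1]]$per_patient$discounted_qalys,
    rc$arms[[2]]$per_patient$discounted_qalys
  )
  expect_equal(rc$ce$delta_qaly, 0)
  expect_equal(rc$ce$delta_cost, 0)
  expect_equal(rc$ce$dominance, "undefined")
  expect_true(is.na(rc$ce$icer))
})

test_that("ICER arithmetic matches a direct-division oracle", {
  expect_equal(
    compare_arms(fake_arm("a", 10.125, 22500), fake_arm("b", 10.0, 20000))$icer,
    20000
  )
  ce <- compare_arms(fake_arm("a", 10 + 0.1081, 22548), fake_arm("b", 10, 20000))
  expect_equal(ce$icer, 2548 / 0.1081)
  expect_equal(round(ce$icer), 23571)

  set.seed(202)
  for (i in 1:25) {
    dq <- runif(1, 0.001, 0.5)
    dc <- runif(1, 1, 5000)
    ce <- compare_arms(fake_arm("a", 10 + dq, 20000 + dc), fake_arm("b", 10, 20000))
    expect_equal(ce$icer, dc / dq, tolerance = 1e-9)
    expect_equal(ce$dominance, "icer")
  }
})

test_that("dominance quadrants are tagged correctly and never divide by zero", {
  base <- fake_arm("b", 10, 20000)
  expect_equal(
    compare_arms(fake_arm("a", 10.1, 19999), base)$dominance,
    "intervention_dominant"
  )
  expect_equal(
    compare_arms(fake_arm("a", 9.9, 20001), base)$dominance,
    "comparator_dominant"
  )
  ud <- compare_arms(fake_arm("a", 10, 25000), base)
  expect_equal(ud$dominance, "undefined")
  expect_true(is.na(ud$icer))
  # southwest quadrant: less effective and cheaper still yields a ratio
  sw <- compare_arms(fake_arm("a", 9.9, 15000), base)
  expect_equal(sw$dominance, "icer")
  expect_equal(sw$icer, -5000 / -0.1)
})

test_that("shorter horizons never increase discounted life expectancy", {
  study <- make_test_study(horizon = 50)
  cats <- default_catalogs(study$config)
  le <- vapply(c(10, 20, 35, 50), function(h) {
    st <- study
    st$config$horizon_years <- as.integer(h)
    out <- run_arm(st, "arm_a", catalogs = cats, n_patients = 150, seed = 8)
    out$summary$mean[out$summary$metric == "discounted_life_years"]
  }, numeric(1))
  expect_true(all(diff(le) >= 0))
  # and 0% discounting can only increase discounted life expectancy
  st0 <- study
  st0$config$discount_rate_effects <- 0
  le0 <- run_arm(st0, "arm_a", catalogs = cats, n_patients = 150, seed = 8)
  le4 <- run_arm(study, "arm_a", catalogs = cats, n_patients = 150, seed = 8)
  expect_gte(
    le0$summary$mean[le0$summary$metric == "discounted_life_years"],
    le4$summary$mean[le4$summary$metric == "discounted_life_years"]
  )
})

test_that("tidy and glance methods return well-formed tibbles", {
  study <- make_test_study(horizon = 8)
  a <- run_arm(study, "arm_a", n_patients = 50, seed = 2)
  td <- tidy(a)
  expect_true(all(c("arm", "metric", "mean", "sd") %in% names(td)))
  expect_true("discounted_qalys" %in% td$metric)
  gl <- glance(a)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$arm, "arm_a")

  b <- run_arm(study, "arm_b", n_patients = 50, seed = 2, comparator = TRUE)
  ce <- compare_arms(a, b)
  expect_equal(nrow(glance(ce)), 1)
  expect_true(all(c("term", "estimate") %in% names(tidy(ce))))
})
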