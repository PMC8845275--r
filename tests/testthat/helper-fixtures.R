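# Shared fixtures: degenerate catalogs and tiny study configurations built
# in code so tests control every hazard source explicitly.

zero_life_table <- function(max_age = 200) {
  life_table(data.frame(
    age_from = 18, age_to = max_age,
    sex = c("male", "female"), q = 0
  ))
}

certain_death_life_table <- function() {
  life_table(data.frame(
    age_from = 18, age_to = 200,
    sex = c("male", "female"), q = 1
  ))
}

flat_life_table <- function(q) {
  life_table(data.frame(
    age_from = 18, age_to = 200,
    sex = c("male", "female"), q = q
  ))
}

empty_risk_catalog <- function() {
  structure(
    list(
      label = "none", events = list(),
      event_fatality = numeric(), mortality = list()
    ),
    class = "risk_catalog"
  )
}

zero_transitions <- function() {
  tabs <- default_transition_tables()
  lapply(tabs, function(tt) {
    tt$p[] <- 0
    tt
  })
}

# A catalog bundle in which nothing ever happens: no events, no background
# mortality, placeholder utilities, zero costs.
inert_catalogs <- function(costs = make_placeholder_cost_catalog(0)) {
  list(
    risk = empty_risk_catalog(),
    transitions = zero_transitions(),
    utilities = default_utility_catalog(),
    costs = costs,
    life_table = zero_life_table()
  )
}

# Single-patient table with explicit defaults; override any field.
patient_row <- function(...) {
  spec <- cohort_spec(
    label = "fixture",
    start_age = c(60, 0), duration = c(8, 0), proportion_male = 1,
    hba1c = c(8, 0), sbp = c(132, 0), bmi = c(30, 0),
    total_cholesterol = c(180, 0), hdl = c(45, 0), egfr = c(90, 0)
  )
  p <- sample_cohort(spec, 1, seed = 1)
  overrides <- list(...)
  for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
  p
}

# Study configuration with a degenerate (all-sd-zero) cohort so every
# patient trajectory is identical up to event draws.
make_test_study <- function(hba1c = 8.0, delta_a = -1.0, delta_b = -0.5,
                            horizon = 10, ...) {
  cohort <- cohort_spec(
    label = "test cohort",
    start_age = c(60, 0), duration = c(8, 0), proportion_male = 0.5,
    hba1c = c(hba1c, 0), sbp = c(132, 0), bmi = c(30, 0),
    total_cholesterol = c(180, 0), hdl = c(45, 0), egfr = c(90, 0)
  )
  arms <- list(
    arm_a = effect_profile("arm_a",
      delta_hba1c = c(delta_a, 0.05),
      delta_bmi = c(-1.5, 0.1),
      annual_therapy_cost_key = "oral_semaglutide"
    ),
    arm_b = effect_profile("arm_b",
      delta_hba1c = c(delta_b, 0.05),
      delta_bmi = c(-0.7, 0.1),
      annual_therapy_cost_key = "empagliflozin"
    )
  )
  structure(
    list(
      comparison = "test",
      cohort = cohort,
      arms = arms,
      config = sim_config(horizon_years = horizon, n_patients = 50, ...)
    ),
    class = "study_config"
  )
}

# Minimal arm_outcome stub for ICER arithmetic tests.
fake_arm <- function(name, qaly, cost, ly = 10) {
  structure(list(
    arm_name = name,
    summary = tibble::tibble(
      metric = c(
        "undiscounted_life_years", "discounted_life_years",
        "discounted_qalys", "discounted_cost_total"
      ),
      mean = c(ly, ly, qaly, cost),
      sd = 0
    )
  ), class = "arm_outcome")
}
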