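#' Baseline cohort specification
#'
#' Describes the joint baseline distribution of a trial cohort: means and
#' standard deviations of the continuous risk factors and the proportions of
#' male and smoking patients. Continuous characteristics are sampled as
#' independent truncated normals by [sample_cohort()]; proportions as
#' independent Bernoulli draws.
#'
#' @param label Free-text label for the cohort.
#' @param start_age,duration,hba1c,sbp,bmi,total_cholesterol,hdl,egfr
#'   Length-2 numeric vectors `c(mean, sd)`. Units: years, years, %, mmHg,
#'   kg/m^2, mg/dL, mg/dL, mL/min/1.73m^2.
#' @param proportion_male,proportion_smoker Fractions in `[0, 1]`.
#' @param cigarettes_per_day Integer count (smokers only).
#' @param alcohol_oz_per_week Ounces of alcohol per week.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(label,
                        start_age, duration, proportion_male,
                        hba1c, sbp, bmi,
                        total_cholesterol = c(180, 40),
                        hdl = c(45, 12),
                        egfr = c(90, 20),
                        proportion_smoker = 0,
                        cigarettes_per_day = 0,
                        alcohol_oz_per_week = 0) {
  pair <- function(x, field, positive_mean = FALSE) {
    if (!is.numeric(x) || length(x) != 2 || anyNA(x)) {
      t2d_validation_error(field, "must be numeric c(mean, sd)")
    }
    if (x[2] < 0) t2d_validation_error(field, "sd must be >= 0")
    if (positive_mean && x[1] <= 0) {
      t2d_validation_error(field, "mean must be strictly positive")
    }
    list(mean = unname(x[1]), sd = unname(x[2]))
  }
  spec <- list(
    label = as.character(label),
    start_age = pair(start_age, "start_age", positive_mean = TRUE),
    duration = pair(duration, "duration"),
    proportion_male = check_fraction(proportion_male, "proportion_male"),
    hba1c = pair(hba1c, "hba1c", positive_mean = TRUE),
    sbp = pair(sbp, "sbp"),
    bmi = pair(bmi, "bmi", positive_mean = TRUE),
    total_cholesterol = pair(total_cholesterol, "total_cholesterol"),
    hdl = pair(hdl, "hdl"),
    egfr = pair(egfr, "egfr"),
    proportion_smoker = check_fraction(proportion_smoker, "proportion_smoker"),
    cigarettes_per_day = as.integer(round(cigarettes_per_day)),
    alcohol_oz_per_week = as.numeric(alcohol_oz_per_week)
  )
  structure(spec, class = "cohort_spec")
}

#' First-year treatment effect profile for one arm
#'
#' Holds the changes from baseline applied in the first simulated year
#' (means with standard errors) and the hypoglycemia rates that apply while
#' the patient remains on the initial therapy.
#'
#' @param arm_name Therapy identifier, also the key into the cost catalog's
#'   `therapy_daily_cost` map unless `annual_therapy_cost_key` overrides it.
#' @param delta_hba1c,delta_sbp,delta_tc,delta_hdl,delta_bmi,delta_egfr
#'   Length-2 numeric vectors `c(mean, se)`; %-points, mmHg, mg/dL, mg/dL,
#'   kg/m^2, mL/min/1.73m^2.
#' @param nonsevere_hypo_rate,severe_hypo_rate Events per 100 patient-years
#'   while on initial therapy.
#' @param nocturnal_fraction_nonsevere,nocturnal_fraction_severe Fractions of
#'   events occurring nocturnally.
#' @param annual_therapy_cost_key Optional cost-catalog key.
#'
#' @return An object of class `effect_profile`.
#' @export
effect_profile <- function(arm_name,
                           delta_hba1c = c(0, 0), delta_sbp = c(0, 0),
                           delta_tc = c(0, 0), delta_hdl = c(0, 0),
                           delta_bmi = c(0, 0), delta_egfr = c(0, 0),
                           nonsevere_hypo_rate = 0, severe_hypo_rate = 0,
                           nocturnal_fraction_nonsevere = 0,
                           nocturnal_fraction_severe = 0,
                           annual_therapy_cost_key = arm_name) {
  pair <- function(x, field) {
    if (!is.numeric(x) || length(x) != 2 || anyNA(x)) {
      t2d_validation_error(field, "must be numeric c(mean, se)")
    }
    if (x[2] < 0) t2d_validation_error(field, "se must be >= 0")
    list(mean = unname(x[1]), se = unname(x[2]))
  }
  structure(list(
    arm_name = as.character(arm_name),
    delta_hba1c = pair(delta_hba1c, "delta_hba1c"),
    delta_sbp = pair(delta_sbp, "delta_sbp"),
    delta_tc = pair(delta_tc, "delta_tc"),
    delta_hdl = pair(delta_hdl, "delta_hdl"),
    delta_bmi = pair(delta_bmi, "delta_bmi"),
    delta_egfr = pair(delta_egfr, "delta_egfr"),
    nonsevere_hypo_rate = check_nonneg(nonsevere_hypo_rate, "nonsevere_hypo_rate"),
    severe_hypo_rate = check_nonneg(severe_hypo_rate, "severe_hypo_rate"),
    nocturnal_fraction_nonsevere =
      check_fraction(nocturnal_fraction_nonsevere, "nocturnal_fraction_nonsevere"),
    nocturnal_fraction_severe =
      check_fraction(nocturnal_fraction_severe, "nocturnal_fraction_severe"),
    annual_therapy_cost_key = as.character(annual_therapy_cost_key)
  ), class = "effect_profile")
}

#' Simulation configuration
#'
#' The knobs of the annual-cycle microsimulation. Defaults correspond to the
#' base-case analysis: 50-year horizon, 4% annual discounting of costs and
#' effects, treatment intensification once HbA1c strictly exceeds 7.5%, an
#' autoregressive (UKPDS-style) HbA1c progression law, BMI treatment effects
#' reverting to baseline on intensification, and basal-insulin hypoglycemia
#' rates of 4.08 (non-severe) and 0.10 (severe) events per patient-year.
#'
#' @param horizon_years Integer number of annual cycles (>= 1).
#' @param discount_rate_costs,discount_rate_effects Annual discount rates.
#' @param n_patients Default first-order cohort size.
#' @param seed Default master seed.
#' @param switch_threshold_hba1c Intensification trigger, %.
#' @param intensification_policy One of `"willis_linear"`, `"target_value"`,
#'   `"none"`.
#' @param hba1c_progression_law One of `"ukpds_ar"`, `"linear"`.
#' @param bmi_persistence `"revert_on_switch"` or `"maintain_lifetime"`.
#' @param risk_set `"ukpds68"` or `"ukpds82"`.
#' @param basal_insulin_hypo_rates Named numeric: `nonsevere`, `severe`
#'   events per patient-year after intensification, plus nocturnal fractions
#'   `nocturnal_fraction_nonsevere`, `nocturnal_fraction_severe`.
#' @param utility_model_bmi `"beaudet"` or `"lee"`.
#' @param hypo_disutility_model `"evans"`, `"currie"` or
#'   `"lauridsen_diminishing"`.
#' @param hba1c_ar Parameters of the autoregressive law:
#'   `weight` (on the previous value, in (0, 1]), `attractor_intercept` (%)
#'   and `attractor_slope` (%-points per year of diabetes duration).
#' @param hba1c_linear_slope Slope (%-points/year) of the linear law.
#' @param willis Intensification-response coefficients for the
#'   `willis_linear` policy: `intercept` and `slope` (per %-point of current
#'   HbA1c); the HbA1c drop is `max(0, intercept + slope * hba1c)`.
#' @param target_hba1c Post-intensification HbA1c for the `target_value`
#'   policy, %.
#' @param forced_switch_years Optional integer: intensify all patients still
#'   on initial therapy at the end of this cycle, regardless of threshold.
#' @param secondary_drift Autoregressive drift parameters for systolic blood
#'   pressure and lipids (`sbp_weight`, `sbp_attractor`, `tc_weight`,
#'   `tc_attractor`, `hdl_weight`, `hdl_attractor`).
#' @param death_accrual `"half"` (dying patients accrue half a cycle of
#'   state utility and state/management/therapy costs) or `"full"`.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(horizon_years = 50,
                       discount_rate_costs = 0.04,
                       discount_rate_effects = 0.04,
                       n_patients = 10000,
                       seed = 20201,
                       switch_threshold_hba1c = 7.5,
                       intensification_policy = c("willis_linear", "target_value", "none"),
                       hba1c_progression_law = c("ukpds_ar", "linear"),
                       bmi_persistence = c("revert_on_switch", "maintain_lifetime"),
                       risk_set = c("ukpds68", "ukpds82"),
                       basal_insulin_hypo_rates = c(
                         nonsevere = 4.08, severe = 0.10,
                         nocturnal_fraction_nonsevere = 0.25,
                         nocturnal_fraction_severe = 0.25
                       ),
                       utility_model_bmi = c("beaudet", "lee"),
                       hypo_disutility_model = c("evans", "currie", "lauridsen_diminishing"),
                       hba1c_ar = c(weight = 0.85, attractor_intercept = 9.5, attractor_slope = 0),
                       hba1c_linear_slope = 0.15,
                       willis = c(intercept = -1.20, slope = 0.30),
                       target_hba1c = 7.0,
                       forced_switch_years = NULL,
                       secondary_drift = c(
                         sbp_weight = 0.95, sbp_attractor = 145,
                         tc_weight = 0.97, tc_attractor = 200,
                         hdl_weight = 0.97, hdl_attractor = 42
                       ),
                       death_accrual = c("half", "full")) {
  if (!is.numeric(horizon_years) || horizon_years < 1) {
    t2d_validation_error("horizon_years", "must be >= 1")
  }
  check_nonneg(discount_rate_costs, "discount_rate_costs")
  check_nonneg(discount_rate_effects, "discount_rate_effects")
  if (!is.numeric(n_patients) || n_patients < 1) {
    t2d_validation_error("n_patients", "must be >= 1")
  }
  check_positive(switch_threshold_hba1c, "switch_threshold_hba1c")
  rates <- basal_insulin_hypo_rates
  for (f in c("nonsevere", "severe")) check_nonneg(rates[[f]], paste0("basal_insulin_hypo_rates$", f))
  structure(list(
    horizon_years = as.integer(horizon_years),
    discount_rate_costs = discount_rate_costs,
    discount_rate_effects = discount_rate_effects,
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    switch_threshold_hba1c = switch_threshold_hba1c,
    intensification_policy = match.arg(intensification_policy),
    hba1c_progression_law = match.arg(hba1c_progression_law),
    bmi_persistence = match.arg(bmi_persistence),
    risk_set = match.arg(risk_set),
    basal_insulin_hypo_rates = rates,
    utility_model_bmi = match.arg(utility_model_bmi),
    hypo_disutility_model = match.arg(hypo_disutility_model),
    hba1c_ar = hba1c_ar,
    hba1c_linear_slope = hba1c_linear_slope,
    willis = willis,
    target_hba1c = target_hba1c,
    forced_switch_years = forced_switch_years,
    secondary_drift = secondary_drift,
    death_accrual = match.arg(death_accrual)
  ), class = "sim_config")
}

#' The progression law implied by a simulation configuration
#' @param config A [sim_config()].
#' @return A [progression_law()] object.
#' @export
config_progression_law <- function(config) {
  if (config$hba1c_progression_law == "ukpds_ar") {
    progression_law(
      "ukpds_ar",
      weight = unname(config$hba1c_ar[["weight"]]),
      attractor_intercept = unname(config$hba1c_ar[["attractor_intercept"]]),
      attractor_slope = unname(config$hba1c_ar[["attractor_slope"]])
    )
  } else {
    progression_law("linear", slope = config$hba1c_linear_slope)
  }
}

#' The intensification policy implied by a simulation configuration
#' @param config A [sim_config()].
#' @return An [intensification_policy()] object.
#' @export
config_intensification_policy <- function(config) {
  switch(config$intensification_policy,
    willis_linear = intensification_policy(
      "willis_linear",
      intercept = unname(config$willis[["intercept"]]),
      slope = unname(config$willis[["slope"]])
    ),
    target_value = intensification_policy("target_value", target = config$target_hba1c),
    none = intensification_policy("none")
  )
}

# ---- packaged study configurations -----------------------------------------

spec_to_list <- function(x) unclass(x)

#' Load a packaged study configuration
#'
#' Reads the packaged parameter file for one of the two comparisons: the
#' head-to-head trial comparison of oral semaglutide 14 mg versus
#' empagliflozin 25 mg (`"pioneer2"`), or the network-meta-analysis
#' comparison versus dulaglutide 1.5 mg with the PIONEER 3 baseline cohort
#' (`"nma"`). Each file carries the published baseline cohort
#' characteristics, the first-year treatment effects (with standard errors)
#' for both arms, and the base-case simulation configuration.
#'
#' @param comparison `"pioneer2"` or `"nma"`.
#' @param path Optional path to a study YAML file; overrides `comparison`
#'   lookup in the package's installed parameter files.
#'
#' @return A list of class `study_config` with elements `comparison`,
#'   `cohort` ([cohort_spec()]), `arms` (named list of two
#'   [effect_profile()]s, intervention first) and `config` ([sim_config()]).
#' @export
load_study_config <- function(comparison = c("pioneer2", "nma"), path = NULL) {
  if (is.null(path)) {
    comparison <- match.arg(comparison)
    path <- system.file("extdata", paste0("study_", comparison, ".yaml"),
      package = "t2dsim", mustWork = TRUE
    )
  }
  raw <- yaml::read_yaml(path)
  for (f in c("comparison", "cohort", "arms", "simulation")) {
    if (is.null(raw[[f]])) t2d_validation_error(f, "missing from study file")
  }
  co <- raw$cohort
  pair <- function(x) c(x$mean, x$sd %||% x$se)
  cohort <- cohort_spec(
    label = co$label,
    start_age = pair(co$start_age),
    duration = pair(co$duration),
    proportion_male = co$proportion_male,
    hba1c = pair(co$hba1c),
    sbp = pair(co$sbp),
    bmi = pair(co$bmi),
    total_cholesterol = pair(co$total_cholesterol),
    hdl = pair(co$hdl),
    egfr = pair(co$egfr),
    proportion_smoker = co$proportion_smoker,
    cigarettes_per_day = co$cigarettes_per_day,
    alcohol_oz_per_week = co$alcohol_oz_per_week
  )
  arms <- lapply(raw$arms, function(a) {
    effect_profile(
      arm_name = a$arm_name,
      delta_hba1c = pair(a$delta_hba1c),
      delta_sbp = pair(a$delta_sbp),
      delta_tc = pair(a$delta_tc),
      delta_hdl = pair(a$delta_hdl),
      delta_bmi = pair(a$delta_bmi),
      delta_egfr = pair(a$delta_egfr),
      nonsevere_hypo_rate = a$nonsevere_hypo_rate,
      severe_hypo_rate = a$severe_hypo_rate,
      nocturnal_fraction_nonsevere = a$nocturnal_fraction_nonsevere,
      nocturnal_fraction_severe = a$nocturnal_fraction_severe,
      annual_therapy_cost_key = a$annual_therapy_cost_key %||% a$arm_name
    )
  })
  names(arms) <- vapply(arms, `[[`, "", "arm_name")
  sc <- raw$simulation
  config <- sim_config(
    horizon_years = sc$horizon_years,
    discount_rate_costs = sc$discount_rate_costs,
    discount_rate_effects = sc$discount_rate_effects,
    n_patients = sc$n_patients,
    seed = sc$seed,
    switch_threshold_hba1c = sc$switch_threshold_hba1c,
    intensification_policy = sc$intensification_policy,
    hba1c_progression_law = sc$hba1c_progression_law,
    bmi_persistence = sc$bmi_persistence,
    risk_set = sc$risk_set,
    basal_insulin_hypo_rates = unlist(sc$basal_insulin_hypo_rates),
    utility_model_bmi = sc$utility_model_bmi,
    hypo_disutility_model = sc$hypo_disutility_model,
    hba1c_ar = unlist(sc$hba1c_ar),
    hba1c_linear_slope = sc$hba1c_linear_slope,
    willis = unlist(sc$willis),
    target_hba1c = sc$target_hba1c,
    forced_switch_years = sc$forced_switch_years,
    secondary_drift = unlist(sc$secondary_drift),
    death_accrual = sc$death_accrual
  )
  structure(
    list(comparison = raw$comparison, cohort = cohort, arms = arms, config = config),
    class = "study_config"
  )
}

#' Write a study configuration to YAML
#'
#' Round-trips with [load_study_config()]: writing then reloading reproduces
#' an equal object.
#'
#' @param study A `study_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(study, path) {
  out <- list(
    comparison = study$comparison,
    cohort = unclass(study$cohort),
    arms = lapply(unname(study$arms), unclass),
    simulation = {
      cfg <- unclass(study$config)
      cfg$basal_insulin_hypo_rates <- as.list(cfg$basal_insulin_hypo_rates)
      cfg$hba1c_ar <- as.list(cfg$hba1c_ar)
      cfg$willis <- as.list(cfg$willis)
      cfg$secondary_drift <- as.list(cfg$secondary_drift)
      cfg
    }
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
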