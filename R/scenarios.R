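# Treatment-effect fields whose between-arm differences were reported as
# statistically significant, by comparison. Used by the
# "statistically significant differences only" scenario: all other
# intervention-arm parameters are set to the comparator's values.
SIGNIFICANT_DELTAS <- list(
  pioneer2 = c("delta_hba1c", "delta_tc", "delta_hdl", "delta_bmi"),
  nma = c("delta_bmi")
)

PROFILE_DELTA_FIELDS <- c(
  "delta_hba1c", "delta_sbp", "delta_tc", "delta_hdl", "delta_bmi", "delta_egfr"
)
PROFILE_RATE_FIELDS <- c(
  "nonsevere_hypo_rate", "severe_hypo_rate",
  "nocturnal_fraction_nonsevere", "nocturnal_fraction_severe"
)

# Shift the intervention arm's delta so the between-arm difference sits at
# the upper (more favourable to the intervention; differences here are
# reductions, so more negative) or lower bound of its 95% CI.
shift_delta_ci <- function(study, field, direction) {
  a <- study$arms[[1]][[field]]
  b <- study$arms[[2]][[field]]
  diff <- a$mean - b$mean
  se <- sqrt(a$se^2 + b$se^2)
  shifted <- diff + if (direction == "upper") -1.96 * se else 1.96 * se
  study$arms[[1]][[field]]$mean <- b$mean + shifted
  study
}

scale_complication_costs <- function(catalogs, factor) {
  catalogs$costs$event_costs <- catalogs$costs$event_costs * factor
  catalogs$costs$state_annual_costs <- catalogs$costs$state_annual_costs * factor
  catalogs
}

scenario_transforms <- function() {
  list(
    base_case = function(study, catalogs) list(study = study, catalogs = catalogs),
    stat_sig_only = function(study, catalogs) {
      sig <- SIGNIFICANT_DELTAS[[study$comparison]] %||% PROFILE_DELTA_FIELDS
      for (f in setdiff(c(PROFILE_DELTA_FIELDS, PROFILE_RATE_FIELDS), sig)) {
        study$arms[[1]][[f]] <- study$arms[[2]][[f]]
      }
      list(study = study, catalogs = catalogs)
    },
    horizon_35 = function(study, catalogs) {
      study$config$horizon_years <- 35L
      list(study = study, catalogs = catalogs)
    },
    horizon_20 = function(study, catalogs) {
      study$config$horizon_years <- 20L
      list(study = study, catalogs = catalogs)
    },
    horizon_10 = function(study, catalogs) {
      study$config$horizon_years <- 10L
      list(study = study, catalogs = catalogs)
    },
    discount_0 = function(study, catalogs) {
      study$config$discount_rate_costs <- 0
      study$config$discount_rate_effects <- 0
      list(study = study, catalogs = catalogs)
    },
    discount_3 = function(study, catalogs) {
      study$config$discount_rate_costs <- 0.03
      study$config$discount_rate_effects <- 0.03
      list(study = study, catalogs = catalogs)
    },
    bmi_lifetime = function(study, catalogs) {
      study$config$bmi_persistence <- "maintain_lifetime"
      list(study = study, catalogs = catalogs)
    },
    no_change_on_switch = function(study, catalogs) {
      study$config$intensification_policy <- "none"
      list(study = study, catalogs = catalogs)
    },
    hba1c_upper_ci = function(study, catalogs) {
      list(study = shift_delta_ci(study, "delta_hba1c", "upper"), catalogs = catalogs)
    },
    hba1c_lower_ci = function(study, catalogs) {
      list(study = shift_delta_ci(study, "delta_hba1c", "lower"), catalogs = catalogs)
    },
    bmi_upper_ci = function(study, catalogs) {
      list(study = shift_delta_ci(study, "delta_bmi", "upper"), catalogs = catalogs)
    },
    bmi_lower_ci = function(study, catalogs) {
      list(study = shift_delta_ci(study, "delta_bmi", "lower"), catalogs = catalogs)
    },
    linear_switch_3y = function(study, catalogs) {
      study$config$hba1c_progression_law <- "linear"
      study$config$forced_switch_years <- 3L
      study$config$intensification_policy <- "target_value"
      study$config$target_hba1c <- 7.0
      list(study = study, catalogs = catalogs)
    },
    costs_plus10 = function(study, catalogs) {
      list(study = study, catalogs = scale_complication_costs(catalogs, 1.1))
    },
    costs_minus10 = function(study, catalogs) {
      list(study = study, catalogs = scale_complication_costs(catalogs, 0.9))
    },
    ukpds82 = function(study, catalogs) {
      study$config$risk_set <- "ukpds82"
      catalogs$risk <- default_risk_coefficients("ukpds82")
      list(study = study, catalogs = catalogs)
    },
    lee_bmi = function(study, catalogs) {
      study$config$utility_model_bmi <- "lee"
      catalogs$utilities$bmi_disutility_per_unit <-
        catalogs$utilities$alternatives$lee_bmi_per_unit
      list(study = study, catalogs = catalogs)
    },
    lauridsen_hypo = function(study, catalogs) {
      study$config$hypo_disutility_model <- "lauridsen_diminishing"
      catalogs$utilities$hypo_model <- "lauridsen_diminishing"
      list(study = study, catalogs = catalogs)
    },
    currie_hypo = function(study, catalogs) {
      study$config$hypo_disutility_model <- "currie"
      catalogs$utilities$hypo_model <- "currie"
      list(study = study, catalogs = catalogs)
    },
    comparator_price_minus10 = function(study, catalogs) {
      catalogs$costs$comparator_price_multiplier <- 0.9
      list(study = study, catalogs = catalogs)
    }
  )
}

#' List the deterministic sensitivity-analysis scenarios
#'
#' @return A tibble with columns `scenario` (tag) and `label`.
#' @export
scenario_definitions <- function() {
  tibble::tibble(
    scenario = names(scenario_transforms()),
    label = c(
      "Base case",
      "Statistically significant differences only",
      "35-year time horizon",
      "20-year time horizon",
      "10-year time horizon",
      "0% discount rates",
      "3% discount rates",
      "BMI treatment effects maintained for patient lifetimes",
      "UKPDS HbA1c progression with no changes on treatment switch",
      "Upper 95% CI of HbA1c estimated treatment difference",
      "Lower 95% CI of HbA1c estimated treatment difference",
      "Upper 95% CI of BMI estimated treatment difference",
      "Lower 95% CI of BMI estimated treatment difference",
      "Treatment switching at 3 years with linear HbA1c progression",
      "Costs of complications +10%",
      "Costs of complications -10%",
      "UKPDS 82 risk equations applied",
      "Lee et al. BMI disutility applied",
      "Lauridsen et al. diminishing hypoglycemia model applied",
      "Currie et al. hypoglycemia disutilities applied",
      "Comparator price reduced by 10%"
    )
  )
}

#' Run the deterministic scenario suite
#'
#' Runs each sensitivity-analysis scenario as a transformation of the base
#' configuration (time horizons, discount rates, BMI persistence,
#' intensification response, treatment-effect confidence bounds, linear
#' progression with fixed-time switching, complication-cost scaling,
#' alternative risk-equation set, alternative disutility models,
#' comparator price discount) with common random-number seeds, and
#' tabulates the incremental outcomes per scenario.
#'
#' @param study A `study_config` or comparison name.
#' @param catalogs Optional catalog bundle.
#' @param scenarios Character vector of scenario tags (default: all).
#' @param n_patients,seed Override the study configuration.
#' @return A tibble with one row per scenario: `scenario`, `label`,
#'   `delta_qaly`, `delta_cost`, `icer`, `dominance`.
#' @export
run_scenario_suite <- function(study = "pioneer2", catalogs = NULL,
                               scenarios = NULL, n_patients = NULL, seed = NULL) {
  if (is.character(study)) study <- load_study_config(study)
  catalogs <- catalogs %||% default_catalogs(study$config)
  transforms <- scenario_transforms()
  scenarios <- scenarios %||% names(transforms)
  unknown <- setdiff(scenarios, names(transforms))
  if (length(unknown)) {
    t2d_argument_error(sprintf(
      "unknown scenario tag(s) %s; valid tags: %s",
      paste0("'", unknown, "'", collapse = ", "),
      paste(names(transforms), collapse = ", ")
    ))
  }
  defs <- scenario_definitions()
  purrr::map_dfr(scenarios, function(tag) {
    tr <- transforms[[tag]](study, catalogs)
    rc <- run_comparison(tr$study,
      catalogs = tr$catalogs,
      n_patients = n_patients, seed = seed
    )
    tibble::tibble(
      scenario = tag,
      label = defs$label[defs$scenario == tag],
      delta_qaly = rc$ce$delta_qaly,
      delta_cost = rc$ce$delta_cost,
      icer = rc$ce$icer,
      dominance = rc$ce$dominance
    )
  })
}

#' Key-driver decomposition
#'
#' Applies the between-arm differences one parameter group at a time: for
#' each driver, every other treatment-effect parameter of the intervention
#' arm is set to the comparator arm's value, and the comparison is re-run
#' on common seeds. Drivers: HbA1c, blood pressure, serum lipids, BMI and
#' hypoglycemia for a trial-based comparison; HbA1c, blood pressure and
#' BMI for the network-meta-analysis comparison (the only outcomes it
#' reported).
#'
#' @param study A `study_config` or comparison name.
#' @param catalogs Optional catalog bundle.
#' @param drivers Character vector of driver tags; defaults by comparison.
#' @param n_patients,seed Override the study configuration.
#' @return A tibble with one row per driver.
#' @export
run_key_drivers <- function(study = "pioneer2", catalogs = NULL, drivers = NULL,
                            n_patients = NULL, seed = NULL) {
  if (is.character(study)) study <- load_study_config(study)
  catalogs <- catalogs %||% default_catalogs(study$config)
  groups <- list(
    hba1c = "delta_hba1c",
    sbp = "delta_sbp",
    lipids = c("delta_tc", "delta_hdl"),
    bmi = "delta_bmi",
    hypo = PROFILE_RATE_FIELDS
  )
  drivers <- drivers %||%
    if (identical(study$comparison, "nma")) c("hba1c", "sbp", "bmi") else names(groups)
  unknown <- setdiff(drivers, names(groups))
  if (length(unknown)) {
    t2d_argument_error(sprintf(
      "unknown driver tag(s) %s; valid tags: %s",
      paste0("'", unknown, "'", collapse = ", "),
      paste(names(groups), collapse = ", ")
    ))
  }
  purrr::map_dfr(drivers, function(d) {
    st <- study
    keep <- groups[[d]]
    for (f in setdiff(c(PROFILE_DELTA_FIELDS, PROFILE_RATE_FIELDS), keep)) {
      st$arms[[1]][[f]] <- st$arms[[2]][[f]]
    }
    rc <- run_comparison(st, catalogs = catalogs, n_patients = n_patients, seed = seed)
    tibble::tibble(
      driver = d,
      delta_qaly = rc$ce$delta_qaly,
      delta_cost = rc$ce$delta_cost,
      icer = rc$ce$icer,
      dominance = rc$ce$dominance
    )
  })
}
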