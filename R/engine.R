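#' Bundle the default catalogs for a simulation
#'
#' @param config A [sim_config()]; selects the risk-equation set and the
#'   BMI/hypoglycemia disutility models.
#' @param costs Optional [cost_catalog()] (default: the placeholder
#'   catalog).
#' @return List with elements `risk`, `transitions`, `utilities`, `costs`,
#'   `life_table`.
#' @export
default_catalogs <- function(config = sim_config(), costs = NULL) {
  utilities <- default_utility_catalog()
  utilities$hypo_model <- config$hypo_disutility_model
  if (config$hypo_disutility_model == "lauridsen_diminishing") {
    # keep the base per-event decrements; only the diminishing ratio applies
  }
  if (config$utility_model_bmi == "lee") {
    utilities$bmi_disutility_per_unit <- utilities$alternatives$lee_bmi_per_unit
  }
  list(
    risk = default_risk_coefficients(config$risk_set),
    transitions = default_transition_tables(),
    utilities = utilities,
    costs = costs %||% make_placeholder_cost_catalog(),
    life_table = default_life_table()
  )
}

TRACKED_COMPLICATIONS <- c(
  "mi", "stroke", "chf", "angina", "pvd", "amputation", "esrd",
  "retinopathy", "macular_edema", "cataract", "neuropathy", "foot_ulcer"
)

complication_present <- function(patients) {
  cbind(
    mi = patients$mi_history,
    stroke = patients$stroke_history,
    chf = patients$chf,
    angina = patients$angina,
    pvd = patients$pvd,
    amputation = patients$foot_stage == "amputated",
    esrd = patients$nephropathy_stage %in% ESRD_STAGES,
    retinopathy = patients$retinopathy_stage != "none",
    macular_edema = patients$macular_edema,
    cataract = patients$cataract,
    neuropathy = patients$neuropathy,
    foot_ulcer = patients$foot_stage %in% c("active_ulcer", "healed_ulcer")
  )
}

# Core annual-cycle loop over a prepared cohort. The random-number stream
# consumes an identical number of draws per cycle regardless of patient
# state, so two runs from the same seed stay aligned draw-for-draw across
# arms and scenarios (common random numbers).
simulate_cohort_cycles <- function(cohort, profile, config, catalogs,
                                   stream_seed, comparator = FALSE,
                                   record_trace = FALSE) {
  patients <- cohort
  n <- nrow(patients)
  patients$pending_switch <- FALSE
  patients$cum_hypo_ns <- 0
  patients$cum_hypo_sev <- 0
  law <- config_progression_law(config)
  policy <- config_intensification_policy(config)
  rates_basal <- config$basal_insulin_hypo_rates
  horizon <- config$horizon_years
  re <- config$discount_rate_effects
  rc <- config$discount_rate_costs
  half <- config$death_accrual == "half"

  disc_ly <- undisc_ly <- disc_qaly <- numeric(n)
  disc_cost <- matrix(0, n, length(COST_CATEGORIES), dimnames = list(NULL, COST_CATEGORIES))
  undisc_cost <- numeric(n)
  years_on_initial <- numeric(n)
  death_year <- rep(NA_real_, n)
  first_year <- matrix(NA_real_, n, length(TRACKED_COMPLICATIONS),
    dimnames = list(NULL, TRACKED_COMPLICATIONS)
  )
  trace <- if (record_trace) vector("list", horizon) else NULL

  with_seed(stream_seed, {
    for (t in seq_len(horizon)) {
      alive <- patients$alive

      # risk-factor progression, then any pending intensification response
      if (t == 1L) {
        patients <- apply_first_year_effects(patients, profile)
      } else {
        patients <- progress_hba1c(patients, law)
        patients <- progress_secondary_factors(patients, config)
      }
      pend <- patients$pending_switch & alive
      if (any(pend)) {
        patients <- apply_intensification(patients, policy,
          bmi_persistence = config$bmi_persistence, who = pend
        )
        patients$pending_switch[pend] <- FALSE
      }

      # recurring (state-level) utility and cost components use the states
      # held at the start of the cycle: post-event states begin next cycle
      patients$events <- rep(list(character()), n)
      patients$hypo_ns_day <- patients$hypo_ns_noct <- 0
      patients$hypo_sev_day <- patients$hypo_sev_noct <- 0
      patients <- annual_therapy_cost(patients, catalogs$costs,
        therapy_key = profile$annual_therapy_cost_key, comparator = comparator
      )
      u_rec <- utility_components(patients, catalogs$utilities)$recurring
      c_rec <- cost_components(patients, catalogs$costs)$recurring

      on_initial <- patients$therapy == "initial"
      patients <- sample_cycle_events(
        patients, catalogs$risk, catalogs$transitions,
        nonsevere_rate = ifelse(on_initial, profile$nonsevere_hypo_rate / 100,
          rates_basal[["nonsevere"]]
        ),
        severe_rate = ifelse(on_initial, profile$severe_hypo_rate / 100,
          rates_basal[["severe"]]
        ),
        nocturnal_fraction_nonsevere = ifelse(on_initial,
          profile$nocturnal_fraction_nonsevere,
          rates_basal[["nocturnal_fraction_nonsevere"]]
        ),
        nocturnal_fraction_severe = ifelse(on_initial,
          profile$nocturnal_fraction_severe,
          rates_basal[["nocturnal_fraction_severe"]]
        )
      )
      u_one <- utility_components(patients, catalogs$utilities)$oneoff
      c_one <- cost_components(patients, catalogs$costs, therapy_cost = numeric(n))$oneoff
      patients$cum_hypo_ns <- patients$cum_hypo_ns +
        patients$hypo_ns_day + patients$hypo_ns_noct
      patients$cum_hypo_sev <- patients$cum_hypo_sev +
        patients$hypo_sev_day + patients$hypo_sev_noct

      # end-of-cycle intensification trigger; takes effect next cycle
      if (!is.null(config$forced_switch_years)) {
        patients$switch_indicated <- alive & on_initial &
          t == config$forced_switch_years
      } else {
        patients <- evaluate_switch(patients, config$switch_threshold_hba1c)
      }
      patients$pending_switch <- patients$pending_switch | patients$switch_indicated

      # mortality: background + acute case fatality + conditional excess
      q <- annual_death_probability(
        patients, catalogs$life_table,
        mortality_eqs = catalogs$risk$mortality,
        events = patients$events,
        fatality = catalogs$risk$event_fatality
      )
      die <- alive & runif(n) < q

      frac <- as.numeric(alive)
      if (half) frac[die] <- 0.5
      df_e <- 1 / (1 + re)^(t - 1)
      df_c <- 1 / (1 + rc)^(t - 1)
      undisc_ly <- undisc_ly + frac
      disc_ly <- disc_ly + frac * df_e
      qaly_cycle <- pmax(frac * u_rec + ifelse(alive, u_one, 0), 0)
      disc_qaly <- disc_qaly + qaly_cycle * df_e
      cost_cycle <- frac * c_rec + as.numeric(alive) * c_one
      disc_cost <- disc_cost + cost_cycle * df_c
      undisc_cost <- undisc_cost + rowSums(cost_cycle)
      years_on_initial <- years_on_initial + (alive & on_initial)

      present <- complication_present(patients)
      newly <- is.na(first_year) & present & alive
      first_year[newly] <- t

      if (record_trace) {
        trace[[t]] <- tibble::tibble(
          cycle = t,
          id = patients$id,
          age = patients$age,
          duration = patients$duration,
          hba1c = patients$hba1c,
          sbp = patients$sbp,
          bmi = patients$bmi,
          therapy = patients$therapy,
          events = vapply(patients$events, paste, "", collapse = ";"),
          hypo_nonsevere = patients$hypo_ns_day + patients$hypo_ns_noct,
          hypo_severe = patients$hypo_sev_day + patients$hypo_sev_noct,
          life_fraction = frac,
          utility = qaly_cycle,
          cost = rowSums(cost_cycle),
          alive_at_end = alive & !die
        )
      }

      death_year[die] <- t
      patients$alive[die] <- FALSE
      surv <- patients$alive
      patients$age[surv] <- patients$age[surv] + 1
      patients$duration[surv] <- patients$duration[surv] + 1
      patients$years_on_therapy[surv] <- patients$years_on_therapy[surv] + 1
    }
  })

  per_patient <- tibble::tibble(
    id = cohort$id,
    undiscounted_life_years = undisc_ly,
    discounted_life_years = disc_ly,
    discounted_qalys = disc_qaly,
    discounted_cost_total = rowSums(disc_cost),
    undiscounted_cost_total = undisc_cost,
    years_on_initial_therapy = years_on_initial,
    death_year = death_year
  )
  for (categ in COST_CATEGORIES) {
    per_patient[[paste0("cost_", categ)]] <- disc_cost[, categ]
  }
  list(
    per_patient = per_patient,
    first_year = first_year,
    trace = if (record_trace) dplyr::bind_rows(trace) else NULL,
    final_state = patients
  )
}

#' Simulate a single patient and return the per-cycle trace
#'
#' Runs the annual-cycle engine for one patient: first-year treatment
#' effects, risk-factor progression, complication and hypoglycemia draws,
#' the intensification trigger, utility and cost accrual (half-cycle in
#' the death year under the default convention) and mortality, until death
#' or the horizon.
#'
#' @param patient One-row patient data frame (see [sample_cohort()]).
#' @param profile An [effect_profile()].
#' @param config A [sim_config()].
#' @param catalogs A catalog bundle from [default_catalogs()].
#' @param seed Integer seed; identical seeds give bitwise-identical traces.
#' @return A tibble with one row per simulated cycle.
#' @export
simulate_patient <- function(patient, profile, config, catalogs = default_catalogs(config),
                             seed = 1L) {
  if (nrow(patient) != 1) t2d_argument_error("`patient` must be a single-row data frame")
  res <- simulate_cohort_cycles(tibble::as_tibble(patient), profile, config, catalogs,
    stream_seed = seed, record_trace = TRUE
  )
  res$trace
}

#' Simulate one treatment arm
#'
#' Samples the baseline cohort (shared across arms through the common
#' `seed`), pushes it through the annual-cycle engine under the arm's
#' treatment-effect profile, and aggregates discounted life-years, QALYs
#' and costs (means and standard deviations across the first-order
#' patients), cumulative complication incidence and mean time to onset,
#' and mean years on initial therapy.
#'
#' Common-random-number discipline: within a comparison, every arm run
#' with the same `seed` consumes the identical baseline cohort and the
#' identical per-patient event-draw streams, so two arms with identical
#' profiles produce identical outcomes.
#'
#' @param study A `study_config` from [load_study_config()].
#' @param arm Arm name (a key of `study$arms`) or an [effect_profile()].
#' @param catalogs Catalog bundle; defaults to [default_catalogs()] under
#'   the study's configuration.
#' @param n_patients Cohort size; defaults to the study configuration's.
#' @param seed Master seed; defaults to the study configuration's.
#' @param comparator Logical: apply the cost catalog's comparator price
#'   multiplier to this arm. Defaults to `TRUE` for the second arm of the
#'   study.
#' @param cohort Optional pre-sampled cohort tibble (overrides sampling).
#' @return An object of class `arm_outcome`.
#' @export
run_arm <- function(study, arm, catalogs = NULL, n_patients = NULL, seed = NULL,
                    comparator = NULL, cohort = NULL) {
  config <- study$config
  profile <- if (inherits(arm, "effect_profile")) arm else {
    study$arms[[arm]] %||% t2d_argument_error(paste0("unknown arm '", arm, "'"))
  }
  catalogs <- catalogs %||% default_catalogs(config)
  n_patients <- n_patients %||% config$n_patients
  seed <- seed %||% config$seed
  comparator <- comparator %||%
    identical(profile$arm_name, names(study$arms)[2])
  cohort <- cohort %||% sample_cohort(study$cohort, n_patients, seed = seed)
  res <- simulate_cohort_cycles(cohort, profile, config, catalogs,
    stream_seed = seed + 1L, comparator = comparator
  )
  pp <- res$per_patient
  metric_cols <- list(
    undiscounted_life_years = pp$undiscounted_life_years,
    discounted_life_years = pp$discounted_life_years,
    discounted_qalys = pp$discounted_qalys,
    discounted_cost_total = pp$discounted_cost_total
  )
  metric_summary <- tibble::tibble(
    metric = names(metric_cols),
    mean = vapply(metric_cols, mean, numeric(1), USE.NAMES = FALSE),
    sd = vapply(metric_cols, stats::sd, numeric(1), USE.NAMES = FALSE)
  )
  incidence <- tibble::tibble(
    complication = TRACKED_COMPLICATIONS,
    cumulative_incidence = colMeans(!is.na(res$first_year)),
    mean_time_to_onset = suppressWarnings(
      apply(res$first_year, 2, function(x) mean(x, na.rm = TRUE))
    )
  )
  cost_by_category <- tibble::tibble(
    category = COST_CATEGORIES,
    mean = vapply(COST_CATEGORIES, function(categ) {
      mean(pp[[paste0("cost_", categ)]])
    }, numeric(1)),
    sd = vapply(COST_CATEGORIES, function(categ) {
      stats::sd(pp[[paste0("cost_", categ)]])
    }, numeric(1))
  )
  structure(list(
    arm_name = profile$arm_name,
    n = nrow(cohort),
    horizon_years = config$horizon_years,
    seed = seed,
    summary = metric_summary,
    cost_by_category = cost_by_category,
    incidence = incidence,
    mean_years_on_initial_therapy = mean(pp$years_on_initial_therapy),
    per_patient = pp
  ), class = "arm_outcome")
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat("<arm_outcome> ", x$arm_name, ": ", x$n, " patients, ",
    x$horizon_years, "-year horizon\n",
    sep = ""
  )
  cat(sprintf(
    "  mean years on initial therapy: %.2f\n",
    x$mean_years_on_initial_therapy
  ))
  print(x$summary)
  invisible(x)
}
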