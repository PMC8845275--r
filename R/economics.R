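# Map from engine state to utility-catalog / cost-catalog state tags.
active_state_tags <- function(patients) {
  n <- nrow(patients)
  tags <- list(
    post_mi = patients$mi_history,
    angina = patients$angina,
    chf = patients$chf,
    post_stroke = patients$stroke_history,
    pvd = patients$pvd,
    microalbuminuria = patients$nephropathy_stage == "microalbuminuria",
    gross_proteinuria = patients$nephropathy_stage == "gross_proteinuria",
    hemodialysis = patients$nephropathy_stage == "esrd_hemodialysis",
    peritoneal_dialysis = patients$nephropathy_stage == "esrd_peritoneal",
    renal_transplant = patients$nephropathy_stage == "esrd_transplant",
    bdr = patients$retinopathy_stage == "bdr",
    pdr = patients$retinopathy_stage == "pdr",
    svl = patients$retinopathy_stage == "svl",
    macular_edema = patients$macular_edema,
    cataract = patients$cataract,
    neuropathy = patients$neuropathy,
    active_ulcer = patients$foot_stage == "active_ulcer",
    healed_ulcer = patients$foot_stage == "healed_ulcer",
    post_amputation = patients$foot_stage == "amputated"
  )
  tags
}

STATE_COST_CATEGORY <- c(
  post_mi = "cardiovascular", angina = "cardiovascular", chf = "cardiovascular",
  post_stroke = "cardiovascular", pvd = "cardiovascular",
  microalbuminuria = "renal", gross_proteinuria = "renal",
  hemodialysis = "renal", peritoneal_dialysis = "renal", renal_transplant = "renal",
  bdr = "ophthalmic", pdr = "ophthalmic", svl = "ophthalmic",
  macular_edema = "ophthalmic", cataract = "ophthalmic",
  neuropathy = "neuropathy_foot", active_ulcer = "neuropathy_foot",
  healed_ulcer = "neuropathy_foot", post_amputation = "neuropathy_foot"
)

EVENT_COST_CATEGORY <- c(
  mi = "cardiovascular", stroke = "cardiovascular", chf = "cardiovascular",
  angina = "cardiovascular", pvd = "cardiovascular",
  renal_failure = "renal", amputation = "neuropathy_foot",
  severe_hypo = "hypoglycemia", nonsevere_hypo = "hypoglycemia"
)

#' Health-state utility catalog
#'
#' Annual health-state utilities, one-off event disutilities (signed,
#' non-positive), hypoglycemia per-event disutilities by severity and time
#' of day, and a BMI disutility per kg/m^2 above the reference. Multiple
#' coexisting states combine by additive decrements from the
#' no-complication baseline, floored at 0.
#'
#' @param baseline_utility Utility with no complications, in `[0, 1]`.
#' @param state_utilities Named numeric vector of annual state utilities.
#' @param event_disutilities Named numeric (signed, `<= 0`) one-off event
#'   decrements.
#' @param hypo_disutilities Named numeric (signed) per-event decrements:
#'   `nonsevere_daytime`, `nonsevere_nocturnal`, `severe_daytime`,
#'   `severe_nocturnal`.
#' @param bmi_disutility_per_unit Signed utility change per kg/m^2 above
#'   `bmi_reference`.
#' @param bmi_reference Reference BMI, kg/m^2.
#' @param hypo_model `"evans"` (constant per-event decrements),
#'   `"currie"` (alternative constants, from `alternatives$currie`) or
#'   `"lauridsen_diminishing"` (per-event decrement shrinking geometrically
#'   with the cumulative event count).
#' @param alternatives List of alternative parameter sets:
#'   `lee_bmi_per_unit`, `currie` (named decrements), `lauridsen_ratio`.
#' @return An object of class `utility_catalog`.
#' @export
utility_catalog <- function(baseline_utility,
                            state_utilities,
                            event_disutilities = numeric(),
                            hypo_disutilities = c(
                              nonsevere_daytime = 0, nonsevere_nocturnal = 0,
                              severe_daytime = 0, severe_nocturnal = 0
                            ),
                            bmi_disutility_per_unit = 0,
                            bmi_reference = 25,
                            hypo_model = "evans",
                            alternatives = list()) {
  check_fraction(baseline_utility, "baseline_utility")
  if (any(event_disutilities > 0)) {
    t2d_validation_error("event_disutilities", "signed decrements must be <= 0")
  }
  structure(list(
    baseline_utility = baseline_utility,
    state_utilities = state_utilities,
    event_disutilities = event_disutilities,
    hypo_disutilities = hypo_disutilities,
    bmi_disutility_per_unit = bmi_disutility_per_unit,
    bmi_reference = bmi_reference,
    hypo_model = hypo_model,
    alternatives = alternatives
  ), class = "utility_catalog")
}

#' Packaged utility catalog
#'
#' The published health-state utilities and event disutilities used in the
#' base case (no-complication baseline 0.785, additive state decrements,
#' per-event hypoglycemia decrements by severity and time of day, and a
#' 0.0061 utility loss per kg/m^2 of BMI above 25), together with the
#' alternative BMI slope, alternative hypoglycemia constants and the
#' diminishing hypoglycemia-disutility model used in scenario analyses.
#'
#' @param path Optional path to a utilities YAML file.
#' @return A [utility_catalog()].
#' @export
default_utility_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "utilities.yaml", package = "t2dsim", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  utility_catalog(
    baseline_utility = raw$baseline_utility,
    state_utilities = unlist(raw$state_utilities),
    event_disutilities = unlist(raw$event_disutilities),
    hypo_disutilities = unlist(raw$hypo_disutilities),
    bmi_disutility_per_unit = raw$bmi_disutility_per_unit,
    bmi_reference = raw$bmi_reference %||% 25,
    hypo_model = raw$hypo_model %||% "evans",
    alternatives = raw$alternatives %||% list()
  )
}

# Sum of additive state decrements (baseline - state utility) per patient.
state_decrement_sum <- function(patients, catalog) {
  tags <- active_state_tags(patients)
  dec <- numeric(nrow(patients))
  for (nm in names(tags)) {
    active <- tags[[nm]]
    if (!any(active)) next
    if (!nm %in% names(catalog$state_utilities)) {
      t2d_config_error(paste0("no state utility entry for tag '", nm, "'"))
    }
    dec <- dec + active * (catalog$baseline_utility - catalog$state_utilities[[nm]])
  }
  dec
}

hypo_decrements <- function(catalog) {
  switch(catalog$hypo_model,
    evans = catalog$hypo_disutilities,
    currie = unlist(catalog$alternatives$currie),
    lauridsen_diminishing = catalog$hypo_disutilities,
    t2d_config_error(paste0("unknown hypo model '", catalog$hypo_model, "'"))
  )
}

# Total (signed) hypoglycemia disutility for count vectors, honoring the
# diminishing model: the i-th lifetime event carries d * ratio^(i - 1), so
# m events after c prior ones contribute d * ratio^c * (1 - ratio^m) / (1 - ratio).
hypo_disutility_total <- function(counts, prior, d, catalog) {
  if (catalog$hypo_model != "lauridsen_diminishing") {
    return(counts * d)
  }
  r <- catalog$alternatives$lauridsen_ratio %||% 0.8
  if (abs(1 - r) < 1e-12) return(counts * d)
  d * r^prior * (1 - r^counts) / (1 - r)
}

# Split the annual utility into a recurring state-level part (baseline
# minus state and BMI decrements) and a one-off signed event part (event
# disutilities + hypoglycemia). The engine weights the recurring part by
# the fraction of the cycle lived; events always count in full.
utility_components <- function(patients, catalog) {
  n <- nrow(patients)
  u <- catalog$baseline_utility - state_decrement_sum(patients, catalog)
  bmi_dis <- catalog$bmi_disutility_per_unit * pmax(patients$bmi - catalog$bmi_reference, 0)
  events <- patients[["events"]] %||% rep(list(character()), n)
  ev_dis <- vapply(events, function(e) {
    e <- e[e %in% names(catalog$event_disutilities)]
    sum(catalog$event_disutilities[e])
  }, numeric(1))
  hd <- hypo_decrements(catalog)
  zero <- numeric(n)
  cnt <- function(col) as.numeric(patients[[col]] %||% zero)
  prior_ns <- cnt("cum_hypo_ns")
  prior_sev <- cnt("cum_hypo_sev")
  hypo_dis <-
    hypo_disutility_total(cnt("hypo_ns_day"), prior_ns, hd[["nonsevere_daytime"]], catalog) +
    hypo_disutility_total(cnt("hypo_ns_noct"), prior_ns, hd[["nonsevere_nocturnal"]], catalog) +
    hypo_disutility_total(cnt("hypo_sev_day"), prior_sev, hd[["severe_daytime"]], catalog) +
    hypo_disutility_total(cnt("hypo_sev_noct"), prior_sev, hd[["severe_nocturnal"]], catalog)
  list(recurring = u + bmi_dis, oneoff = ev_dis + hypo_dis)
}

#' Annual utility of a patient-year
#'
#' Baseline utility minus additive state decrements (one
#' `baseline - state utility` term per active chronic state), minus this
#' cycle's one-off event disutilities, minus per-event hypoglycemia
#' decrements, minus the BMI decrement
#' `|bmi_disutility_per_unit| * max(0, BMI - reference)`; floored at 0.
#' Event tags are read from the `events` list-column and hypoglycemia
#' counts from the `hypo_*` columns if present (see
#' [sample_cycle_events()]); otherwise the patient-year is event-free.
#'
#' @param patients Patient data frame.
#' @param catalog A [utility_catalog()].
#' @return The patient tibble with a `utility` column.
#' @export
annual_utility <- function(patients, catalog) {
  comp <- utility_components(patients, catalog)
  patients$utility <- pmax(comp$recurring + comp$oneoff, 0)
  tibble::as_tibble(patients)
}

#' Annual cost of a patient-year, by category
#'
#' Therapy acquisition cost plus annual management cost plus one-off costs
#' of this cycle's events plus annual costs of active chronic states,
#' broken down into the categories treatment, management, hypoglycemia,
#' cardiovascular, renal, ophthalmic and neuropathy/foot.
#'
#' @param patients Patient data frame; event tags are read from the
#'   `events` list-column and hypoglycemia counts from the `hypo_*`
#'   columns if present.
#' @param catalog A [cost_catalog()].
#' @param therapy_cost Annual therapy cost per patient; defaults to the
#'   `therapy_cost` column (see [annual_therapy_cost()]), else 0.
#' @return The patient tibble with columns `cost_treatment`,
#'   `cost_management`, `cost_hypoglycemia`, `cost_cardiovascular`,
#'   `cost_renal`, `cost_ophthalmic`, `cost_neuropathy_foot` and
#'   `cost_total`.
#' @export
annual_cost <- function(patients, catalog, therapy_cost = NULL) {
  comp <- cost_components(patients, catalog, therapy_cost)
  cat_cost <- comp$recurring + comp$oneoff
  for (categ in COST_CATEGORIES) {
    patients[[paste0("cost_", categ)]] <- unname(cat_cost[, categ])
  }
  patients$cost_total <- unname(rowSums(cat_cost))
  tibble::as_tibble(patients)
}

# Recurring (therapy + management + chronic-state) and one-off (event +
# hypoglycemia) cost matrices by category; the engine weights recurring
# costs by the fraction of the cycle lived.
cost_components <- function(patients, catalog, therapy_cost = NULL) {
  n <- nrow(patients)
  therapy_cost <- therapy_cost %||% patients[["therapy_cost"]] %||% numeric(n)
  recurring <- matrix(0, n, length(COST_CATEGORIES),
    dimnames = list(NULL, COST_CATEGORIES)
  )
  oneoff <- recurring
  recurring[, "treatment"] <- therapy_cost
  recurring[, "management"] <- catalog$management_annual_cost

  events <- patients[["events"]] %||% rep(list(character()), n)
  for (tag in names(catalog$event_costs)) {
    if (tag %in% c("severe_hypo", "nonsevere_hypo")) next
    hit <- vapply(events, function(e) sum(e == tag), numeric(1))
    if (!any(hit > 0)) next
    categ <- EVENT_COST_CATEGORY[[tag]] %||%
      t2d_config_error(paste0("no cost category for event tag '", tag, "'"))
    oneoff[, categ] <- oneoff[, categ] + hit * catalog$event_costs[[tag]]
  }
  zero <- numeric(n)
  cnt <- function(col) as.numeric(patients[[col]] %||% zero)
  n_sev <- cnt("hypo_sev_day") + cnt("hypo_sev_noct")
  n_ns <- cnt("hypo_ns_day") + cnt("hypo_ns_noct")
  oneoff[, "hypoglycemia"] <- oneoff[, "hypoglycemia"] +
    n_sev * (catalog$event_costs[["severe_hypo"]] %||% 0) +
    n_ns * (catalog$event_costs[["nonsevere_hypo"]] %||% 0)

  tags <- active_state_tags(patients)
  for (nm in names(tags)) {
    active <- tags[[nm]]
    if (!any(active)) next
    if (!nm %in% names(catalog$state_annual_costs)) {
      t2d_config_error(paste0("no state_annual_costs entry for tag '", nm, "'"))
    }
    categ <- STATE_COST_CATEGORY[[nm]]
    recurring[, categ] <- recurring[, categ] + active * catalog$state_annual_costs[[nm]]
  }
  list(recurring = recurring, oneoff = oneoff)
}

#' Present value of an annual stream
#'
#' `sum(value_t / (1 + rate)^(t - 1))`: the first cycle is undiscounted.
#' A rate of 0 returns the arithmetic sum.
#'
#' @param values Numeric vector, one value per annual cycle.
#' @param rate Annual discount rate (>= 0).
#' @return The present value (a single number).
#' @export
discount_stream <- function(values, rate) {
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) || rate < 0) {
    t2d_argument_error("`rate` must be a non-negative number")
  }
  if (!length(values)) return(0)
  sum(values / (1 + rate)^(seq_along(values) - 1))
}
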