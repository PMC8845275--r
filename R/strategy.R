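#' Cost catalog
#'
#' Unit costs consumed by the simulation: daily therapy acquisition costs,
#' basal-insulin consumables (insulin per IU, one needle and one
#' self-monitoring blood-glucose strip per day), one-off event costs,
#' annual chronic-state costs and an annual patient-management cost. All
#' costs must be non-negative; every event and state tag used by the
#' engine must have an entry.
#'
#' @param currency_label Free text, e.g. `"EUR 2021"`.
#' @param therapy_daily_cost Named numeric: cost per day by therapy key.
#' @param insulin_cost_per_iu,needle_cost,smbg_strip_cost Unit costs of the
#'   basal-insulin consumables.
#' @param insulin_daily_iu Defined daily dose of basal insulin, IU.
#' @param event_costs Named numeric: one-off cost per event tag.
#' @param state_annual_costs Named numeric: annual cost per chronic-state
#'   tag.
#' @param management_annual_cost Annual patient-management cost.
#' @param comparator_price_multiplier Factor applied to the comparator
#'   arm's therapy acquisition cost (price-discount scenarios).
#' @return An object of class `cost_catalog`.
#' @export
cost_catalog <- function(currency_label = "placeholder units",
                         therapy_daily_cost = numeric(),
                         insulin_cost_per_iu = 0,
                         needle_cost = 0,
                         smbg_strip_cost = 0,
                         insulin_daily_iu = 40,
                         event_costs = numeric(),
                         state_annual_costs = numeric(),
                         management_annual_cost = 0,
                         comparator_price_multiplier = 1) {
  allc <- c(
    therapy_daily_cost, insulin_cost_per_iu, needle_cost, smbg_strip_cost,
    event_costs, state_annual_costs, management_annual_cost
  )
  if (any(allc < 0)) t2d_validation_error("costs", "all costs must be >= 0")
  structure(list(
    currency_label = currency_label,
    therapy_daily_cost = therapy_daily_cost,
    insulin_cost_per_iu = insulin_cost_per_iu,
    needle_cost = needle_cost,
    smbg_strip_cost = smbg_strip_cost,
    insulin_daily_iu = insulin_daily_iu,
    event_costs = event_costs,
    state_annual_costs = state_annual_costs,
    management_annual_cost = management_annual_cost,
    comparator_price_multiplier = comparator_price_multiplier
  ), class = "cost_catalog")
}

#' Placeholder cost catalog
#'
#' A complete, documented catalog with one nonzero entry per therapy, per
#' complication event, per chronic complication state-year and per
#' management item, all multiplied by `scale`. The schema is exactly what a
#' user would fill with real national tariffs; the shipped magnitudes are
#' placeholders (the original analysis used unpublished Portuguese unit
#' costs), so absolute cost outputs are only meaningful relative to a
#' user-supplied catalog.
#'
#' @param scale Currency scale factor (>= 0); `scale = 0` yields an
#'   all-zero catalog (and hence zero simulated cost differences).
#' @return A [cost_catalog()].
#' @export
make_placeholder_cost_catalog <- function(scale = 1) {
  if (!is.numeric(scale) || length(scale) != 1 || is.na(scale) || scale < 0) {
    t2d_argument_error("`scale` must be a non-negative number")
  }
  cost_catalog(
    currency_label = sprintf("placeholder units (scale %g)", scale),
    therapy_daily_cost = scale * c(
      oral_semaglutide = 2.80,
      empagliflozin = 1.20,
      dulaglutide = 2.60
    ),
    insulin_cost_per_iu = scale * 0.025,
    needle_cost = scale * 0.10,
    smbg_strip_cost = scale * 0.25,
    insulin_daily_iu = 40,
    event_costs = scale * c(
      mi = 4500, stroke = 5500, chf = 3500, angina = 2500, pvd = 2000,
      renal_failure = 3000, amputation = 9000,
      severe_hypo = 400, nonsevere_hypo = 2
    ),
    state_annual_costs = scale * c(
      post_mi = 800, post_stroke = 1500, chf = 1200, angina = 500, pvd = 400,
      microalbuminuria = 50, gross_proteinuria = 300,
      hemodialysis = 32000, peritoneal_dialysis = 28000, renal_transplant = 6000,
      bdr = 100, pdr = 350, svl = 900, macular_edema = 300, cataract = 60,
      neuropathy = 350, active_ulcer = 2000, healed_ulcer = 100,
      post_amputation = 1200
    ),
    management_annual_cost = scale * 450,
    comparator_price_multiplier = 1
  )
}

#' Evaluate the treatment-intensification trigger
#'
#' A patient switches to basal insulin if and only if they are on initial
#' therapy and their end-of-cycle HbA1c strictly exceeds the threshold.
#' Patients already on basal insulin never switch again (the therapy state
#' is absorbing).
#'
#' @param patients Patient data frame.
#' @param threshold Switch threshold, % HbA1c (base case 7.5).
#' @return The patient tibble with a logical `switch_indicated` column.
#' @export
evaluate_switch <- function(patients, threshold = 7.5) {
  alive <- patients[["alive"]] %||% rep(TRUE, nrow(patients))
  patients$switch_indicated <- alive &
    patients$therapy == "initial" &
    patients$hba1c > threshold
  tibble::as_tibble(patients)
}

#' Annual therapy acquisition cost
#'
#' On initial therapy: 365.25 days times the arm's daily drug cost (no
#' needles or glucose strips; oral and pre-packaged injectable therapies
#' carry their consumables). On basal insulin: 365.25 times the daily cost
#' of the defined daily dose of insulin plus one needle and one
#' self-monitoring test per day. The comparator arm's acquisition cost is
#' multiplied by the catalog's `comparator_price_multiplier`.
#'
#' @param patients Patient data frame (columns `therapy`, `alive`).
#' @param catalog A [cost_catalog()].
#' @param therapy_key Cost-catalog key of the arm's initial therapy.
#' @param comparator Logical: is this the comparator arm? (applies the
#'   price multiplier).
#' @return The patient tibble with a `therapy_cost` column (cost/year).
#' @export
annual_therapy_cost <- function(patients, catalog, therapy_key,
                                comparator = FALSE) {
  if (!therapy_key %in% names(catalog$therapy_daily_cost)) {
    t2d_config_error(paste0("no therapy_daily_cost entry for key '", therapy_key, "'"))
  }
  daily_initial <- catalog$therapy_daily_cost[[therapy_key]] *
    (if (comparator) catalog$comparator_price_multiplier else 1)
  daily_basal <- catalog$insulin_daily_iu * catalog$insulin_cost_per_iu +
    catalog$needle_cost + catalog$smbg_strip_cost
  patients$therapy_cost <- 365.25 *
    ifelse(patients$therapy == "initial", daily_initial, daily_basal)
  tibble::as_tibble(patients)
}
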