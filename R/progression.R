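#' HbA1c progression law
#'
#' Two functional forms for annual HbA1c progression after the first year.
#' The autoregressive form (`"ukpds_ar"`) pulls the current value toward a
#' duration-dependent attractor:
#' `new = w * current + (1 - w) * (intercept + slope * duration)`,
#' which is strictly increasing whenever the current value lies below the
#' attractor, emulating the gradual loss of glycemic control seen in
#' long-run type 2 diabetes cohorts while between-arm differences decay
#' geometrically at rate `w`. The `"linear"` form adds a constant slope.
#'
#' @param kind `"ukpds_ar"` or `"linear"`.
#' @param weight Autoregression weight on the previous value, in `(0, 1]`.
#' @param attractor_intercept Attractor level at duration 0, %.
#' @param attractor_slope Attractor increase per year of diabetes duration.
#' @param slope Linear slope, %-points/year.
#' @return An object of class `progression_law`.
#' @export
progression_law <- function(kind = c("ukpds_ar", "linear"),
                            weight = 0.85, attractor_intercept = 9.5,
                            attractor_slope = 0, slope = 0.15) {
  kind <- match.arg(kind)
  if (kind == "ukpds_ar") {
    if (!is.numeric(weight) || weight <= 0 || weight > 1) {
      t2d_validation_error("weight", "autoregression weight must lie in (0, 1]")
    }
    if (!all(is.finite(c(attractor_intercept, attractor_slope)))) {
      t2d_validation_error("attractor", "parameters must be finite")
    }
  }
  structure(list(
    kind = kind, weight = weight,
    attractor_intercept = attractor_intercept,
    attractor_slope = attractor_slope,
    slope = slope
  ), class = "progression_law")
}

#' Treatment-intensification response policy
#'
#' How HbA1c responds when a patient intensifies to basal insulin:
#' `"willis_linear"` applies a drop of `max(0, intercept + slope * HbA1c)`
#' (a multivariate-equation style response for an insulin-naive population,
#' coefficients user-editable and never negative in effect);
#' `"target_value"` sets HbA1c to a fixed post-switch value; `"none"`
#' leaves HbA1c unchanged.
#'
#' @param kind `"willis_linear"`, `"target_value"` or `"none"`.
#' @param intercept,slope Coefficients of the linear drop.
#' @param target Post-switch HbA1c for `"target_value"`, % (> 0).
#' @return An object of class `intensification_policy`.
#' @export
intensification_policy <- function(kind = c("willis_linear", "target_value", "none"),
                                   intercept = -1.20, slope = 0.30,
                                   target = 7.0) {
  kind <- match.arg(kind)
  if (kind == "target_value") check_positive(target, "target")
  structure(list(kind = kind, intercept = intercept, slope = slope, target = target),
    class = "intensification_policy"
  )
}

#' Apply first-year treatment effects
#'
#' Adds each arm's change-from-baseline (HbA1c, systolic blood pressure,
#' total and HDL cholesterol, BMI, eGFR) to the corresponding patient
#' field. Applied once, in cycle 1, while patients are on initial therapy;
#' zero deltas (e.g. parameters not modelled in a network meta-analysis)
#' leave fields unchanged.
#'
#' @param patients Patient data frame.
#' @param profile An [effect_profile()].
#' @return The patient tibble with updated risk factors.
#' @export
apply_first_year_effects <- function(patients, profile) {
  patients$hba1c <- patients$hba1c + profile$delta_hba1c$mean
  patients$sbp <- patients$sbp + profile$delta_sbp$mean
  patients$tc <- patients$tc + profile$delta_tc$mean
  patients$hdl <- patients$hdl + profile$delta_hdl$mean
  patients$bmi <- patients$bmi + profile$delta_bmi$mean
  patients$egfr <- patients$egfr + profile$delta_egfr$mean
  tibble::as_tibble(patients)
}

#' Progress HbA1c by one annual cycle
#'
#' Applies a [progression_law()] to every alive patient (cycle 2 onward).
#' Values never become negative.
#'
#' @param patients Patient data frame.
#' @param law A [progression_law()].
#' @return The patient tibble with updated `hba1c`.
#' @export
progress_hba1c <- function(patients, law) {
  alive <- patients[["alive"]] %||% rep(TRUE, nrow(patients))
  new <- if (law$kind == "ukpds_ar") {
    attractor <- law$attractor_intercept + law$attractor_slope * patients$duration
    law$weight * patients$hba1c + (1 - law$weight) * attractor
  } else {
    patients$hba1c + law$slope
  }
  patients$hba1c <- ifelse(alive, pmax(new, 0), patients$hba1c)
  tibble::as_tibble(patients)
}

#' Apply treatment intensification
#'
#' Switches the selected patients to basal insulin: therapy becomes
#' `"basal_insulin"`, HbA1c is reduced according to the
#' [intensification_policy()], the years-on-therapy clock restarts and,
#' under `bmi_persistence = "revert_on_switch"`, BMI reverts to its
#' baseline value (treatment effects on weight are lost when the initial
#' therapy stops).
#'
#' @param patients Patient data frame.
#' @param policy An [intensification_policy()].
#' @param bmi_persistence `"revert_on_switch"` or `"maintain_lifetime"`.
#' @param who Logical vector selecting patients to intensify (default: all
#'   rows).
#' @return The patient tibble with updated therapy state.
#' @export
apply_intensification <- function(patients, policy,
                                  bmi_persistence = c("revert_on_switch", "maintain_lifetime"),
                                  who = NULL) {
  bmi_persistence <- match.arg(bmi_persistence)
  who <- who %||% rep(TRUE, nrow(patients))
  if (!any(who)) return(tibble::as_tibble(patients))
  h <- patients$hba1c[who]
  new_h <- switch(policy$kind,
    willis_linear = h - pmax(policy$intercept + policy$slope * h, 0),
    target_value = rep(policy$target, sum(who)),
    none = h
  )
  patients$hba1c[who] <- pmax(new_h, 0)
  patients$therapy[who] <- "basal_insulin"
  patients$years_on_therapy[who] <- 0
  if (bmi_persistence == "revert_on_switch") {
    patients$bmi[who] <- patients$baseline_bmi[who]
  }
  tibble::as_tibble(patients)
}

#' Progress blood pressure and serum lipids by one cycle
#'
#' Systolic blood pressure, total cholesterol and HDL drift toward
#' configurable attractors under the same autoregressive form as HbA1c
#' (natural-progression stand-ins for the UKPDS/Framingham algorithms).
#' BMI is held at its treated value while on initial therapy (or for life
#' under `maintain_lifetime`); reversion on switch is handled by
#' [apply_intensification()]. eGFR is carried but not progressed. No risk
#' factor ever becomes negative.
#'
#' @param patients Patient data frame.
#' @param config A [sim_config()] (its `secondary_drift` entry supplies the
#'   weights and attractors).
#' @return The patient tibble with updated `sbp`, `tc`, `hdl`.
#' @export
progress_secondary_factors <- function(patients, config) {
  d <- config$secondary_drift
  alive <- patients[["alive"]] %||% rep(TRUE, nrow(patients))
  ar <- function(x, w, attractor) pmax(w * x + (1 - w) * attractor, 0)
  patients$sbp <- ifelse(alive, ar(patients$sbp, d[["sbp_weight"]], d[["sbp_attractor"]]), patients$sbp)
  patients$tc <- ifelse(alive, ar(patients$tc, d[["tc_weight"]], d[["tc_attractor"]]), patients$tc)
  patients$hdl <- ifelse(alive, ar(patients$hdl, d[["hdl_weight"]], d[["hdl_attractor"]]), patients$hdl)
  tibble::as_tibble(patients)
}
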