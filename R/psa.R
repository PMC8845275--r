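# Scaled-beta draw for a utility decrement: mean d, sd frac * d, support
# [0, 1]. Degenerate inputs return the mean (collapsed distribution).
draw_decrement <- function(d, frac) {
  d <- abs(d)
  if (d <= 0 || frac <= 0) return(d)
  v <- (frac * d)^2
  if (v >= d * (1 - d)) return(d)
  k <- d * (1 - d) / v - 1
  stats::rbeta(1, d * k, (1 - d) * k)
}

# Gamma draw with mean m and coefficient of variation cv (mean-preserving).
draw_cost <- function(m, cv) {
  if (m <= 0 || cv <= 0) return(m)
  shape <- 1 / cv^2
  stats::rgamma(1, shape = shape, scale = m / shape)
}

perturb_profile <- function(profile) {
  for (f in c("delta_hba1c", "delta_sbp", "delta_tc", "delta_hdl", "delta_bmi", "delta_egfr")) {
    profile[[f]]$mean <- stats::rnorm(1, profile[[f]]$mean, profile[[f]]$se)
  }
  profile
}

perturb_costs <- function(costs, cv) {
  costs$event_costs <- vapply(costs$event_costs, draw_cost, numeric(1), cv = cv)
  costs$state_annual_costs <- vapply(costs$state_annual_costs, draw_cost, numeric(1), cv = cv)
  costs$management_annual_cost <- draw_cost(costs$management_annual_cost, cv)
  costs
}

perturb_utilities <- function(utilities, frac) {
  base <- utilities$baseline_utility
  utilities$state_utilities <- vapply(names(utilities$state_utilities), function(nm) {
    base - draw_decrement(base - utilities$state_utilities[[nm]], frac)
  }, numeric(1))
  utilities$event_disutilities <- vapply(utilities$event_disutilities,
    function(d) -draw_decrement(-d, frac), numeric(1)
  )
  utilities$hypo_disutilities <- vapply(utilities$hypo_disutilities,
    function(d) -draw_decrement(-d, frac), numeric(1)
  )
  utilities$bmi_disutility_per_unit <- -draw_decrement(-utilities$bmi_disutility_per_unit, frac)
  utilities
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Per iteration, draws the second-order parameters — treatment-effect
#' means from normal distributions with their published standard errors,
#' complication cost entries from gamma distributions (default coefficient
#' of variation 20%) and utility decrements from scaled beta distributions
#' (default sd 10% of the decrement) — then runs a reduced-size
#' first-order simulation of both arms under common random numbers and
#' records the incremental cost and QALY pair. Returns the scatter, the
#' cost-effectiveness acceptability curve (fraction of iterations with
#' positive net monetary benefit at each willingness-to-pay) and the
#' PSA point estimate (means over iterations).
#'
#' @param study A `study_config` or comparison name.
#' @param catalogs Optional catalog bundle.
#' @param n_iterations Number of second-order iterations (>= 2).
#' @param n_patients First-order patients per iteration (default 500).
#' @param seed Master seed.
#' @param wtp Willingness-to-pay grid for the CEAC.
#' @param cost_cv Coefficient of variation of cost entries.
#' @param utility_sd_frac Sd of utility decrements as a fraction of the
#'   decrement.
#' @return A `ce_result` whose `scatter` holds one row per iteration and
#'   whose `ceac` holds the acceptability curve; `delta_qaly`,
#'   `delta_cost` and `icer` are means over iterations.
#' @export
run_psa <- function(study = "pioneer2", catalogs = NULL,
                    n_iterations = 200, n_patients = 500, seed = NULL,
                    wtp = seq(0, 60000, by = 2000),
                    cost_cv = 0.2, utility_sd_frac = 0.1) {
  if (is.character(study)) study <- load_study_config(study)
  if (n_iterations < 2) t2d_argument_error("`n_iterations` must be >= 2")
  catalogs <- catalogs %||% default_catalogs(study$config)
  seed <- seed %||% study$config$seed
  arm_names <- names(study$arms)
  rows <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    study_i <- study
    catalogs_i <- catalogs
    with_seed(seed + 100000L + i, {
      study_i$arms <- lapply(study$arms, perturb_profile)
      catalogs_i$costs <- perturb_costs(catalogs$costs, cost_cv)
      catalogs_i$utilities <- perturb_utilities(catalogs$utilities, utility_sd_frac)
    })
    rc <- run_comparison(study_i,
      catalogs = catalogs_i,
      n_patients = n_patients, seed = seed + i
    )
    rows[[i]] <- tibble::tibble(
      iteration = i,
      delta_qaly = rc$ce$delta_qaly,
      delta_cost = rc$ce$delta_cost
    )
  }
  scatter <- dplyr::bind_rows(rows)
  dq <- mean(scatter$delta_qaly)
  dc <- mean(scatter$delta_cost)
  out <- structure(list(
    intervention = arm_names[1],
    comparator = arm_names[2],
    delta_qaly = dq,
    delta_cost = dc,
    delta_ly = NA_real_,
    icer = if (dq > 0 && dc > 0) dc / dq else NA_real_,
    dominance = if (dq > 0 && dc > 0) "icer" else if (dq == 0) "undefined" else if (dq > 0) "intervention_dominant" else "comparator_dominant",
    scatter = scatter,
    ceac = ceac_curve(scatter, wtp)
  ), class = c("psa_result", "ce_result"))
  out
}
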