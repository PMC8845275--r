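#' Compare two simulated arms
#'
#' Computes incremental outcomes of the first (intervention) arm over the
#' second (comparator): difference in mean discounted QALYs, difference in
#' mean discounted total cost, and the incremental cost-effectiveness
#' ratio (ICER) or a dominance tag. Quadrant conventions: more effective
#' and more costly (or less effective and less costly) gives an ICER;
#' more effective and no more costly is `intervention_dominant`; less
#' effective and at least as costly is `comparator_dominant`; equal
#' effectiveness yields an explicit `undefined` result (never a division
#' by zero).
#'
#' @param a,b [run_arm()] outcomes for the intervention and comparator.
#' @return An object of class `ce_result` with elements `delta_qaly`,
#'   `delta_cost`, `delta_ly`, `icer`, `dominance` and the two arm names.
#' @export
compare_arms <- function(a, b) {
  stat <- function(x, m) unname(x$summary$mean[x$summary$metric == m])
  dq <- stat(a, "discounted_qalys") - stat(b, "discounted_qalys")
  dc <- stat(a, "discounted_cost_total") - stat(b, "discounted_cost_total")
  dl <- stat(a, "discounted_life_years") - stat(b, "discounted_life_years")
  if (dq == 0) {
    dominance <- "undefined"
    icer <- NA_real_
  } else if (dq > 0 && dc <= 0) {
    dominance <- "intervention_dominant"
    icer <- NA_real_
  } else if (dq < 0 && dc >= 0) {
    dominance <- "comparator_dominant"
    icer <- NA_real_
  } else {
    dominance <- "icer"
    icer <- dc / dq
  }
  structure(list(
    intervention = a$arm_name,
    comparator = b$arm_name,
    delta_qaly = dq,
    delta_cost = dc,
    delta_ly = dl,
    icer = icer,
    dominance = dominance,
    scatter = NULL,
    ceac = NULL
  ), class = "ce_result")
}

#' Run a full two-arm comparison
#'
#' Convenience wrapper: loads (or accepts) a study configuration, runs
#' both arms on the shared cohort and common random-number streams, and
#' compares them.
#'
#' @param study A `study_config` or a comparison name (`"pioneer2"`,
#'   `"nma"`).
#' @param catalogs Optional catalog bundle.
#' @param n_patients,seed Override the study configuration.
#' @return List with `arms` (named list of `arm_outcome`) and `ce`
#'   (`ce_result`).
#' @export
run_comparison <- function(study = "pioneer2", catalogs = NULL,
                           n_patients = NULL, seed = NULL) {
  if (is.character(study)) study <- load_study_config(study)
  catalogs <- catalogs %||% default_catalogs(study$config)
  arm_names <- names(study$arms)
  arms <- list(
    run_arm(study, arm_names[1],
      catalogs = catalogs, n_patients = n_patients,
      seed = seed, comparator = FALSE
    ),
    run_arm(study, arm_names[2],
      catalogs = catalogs, n_patients = n_patients,
      seed = seed, comparator = TRUE
    )
  )
  names(arms) <- arm_names
  list(arms = arms, ce = compare_arms(arms[[1]], arms[[2]]))
}

#' Cost-effectiveness acceptability curve from a PSA scatter
#'
#' For each willingness-to-pay value, the probability of the intervention
#' being cost-effective is the fraction of iterations with positive net
#' monetary benefit, `wtp * delta_qaly - delta_cost > 0`.
#'
#' @param scatter Data frame with columns `delta_qaly`, `delta_cost`.
#' @param wtp Numeric vector of willingness-to-pay thresholds per QALY.
#' @return Tibble with columns `wtp`, `probability_cost_effective`.
#' @export
ceac_curve <- function(scatter, wtp = seq(0, 60000, by = 2000)) {
  tibble::tibble(
    wtp = wtp,
    probability_cost_effective = vapply(wtp, function(w) {
      mean(w * scatter$delta_qaly - scatter$delta_cost > 0)
    }, numeric(1))
  )
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result> ", x$intervention, " vs ", x$comparator, "\n", sep = "")
  cat(sprintf("  delta QALYs: %+.4f\n  delta cost:  %+.2f\n", x$delta_qaly, x$delta_cost))
  if (x$dominance == "icer") {
    cat(sprintf("  ICER: %.0f per QALY gained\n", x$icer))
  } else {
    cat("  dominance: ", x$dominance, "\n", sep = "")
  }
  if (!is.null(x$scatter)) {
    cat("  PSA iterations: ", nrow(x$scatter), "\n", sep = "")
  }
  invisible(x)
}

# ---- broom-style methods ----------------------------------------------------

#' Tidy an arm outcome
#'
#' @param x An `arm_outcome`.
#' @param ... Unused.
#' @return A tibble of outcome metrics (mean and across-patient sd).
#' @export
tidy.arm_outcome <- function(x, ...) {
  dplyr::bind_rows(
    x$summary,
    x$cost_by_category |>
      dplyr::transmute(
        metric = paste0("discounted_cost_", .data$category),
        mean = .data$mean, sd = .data$sd
      ),
    tibble::tibble(
      metric = "years_on_initial_therapy",
      mean = x$mean_years_on_initial_therapy,
      sd = stats::sd(x$per_patient$years_on_initial_therapy)
    )
  ) |>
    dplyr::mutate(arm = x$arm_name, .before = 1)
}

#' @rdname tidy.arm_outcome
#' @export
glance.arm_outcome <- function(x, ...) {
  s <- function(m) x$summary$mean[x$summary$metric == m]
  tibble::tibble(
    arm = x$arm_name,
    n = x$n,
    horizon_years = x$horizon_years,
    discounted_life_years = s("discounted_life_years"),
    discounted_qalys = s("discounted_qalys"),
    discounted_cost_total = s("discounted_cost_total"),
    years_on_initial_therapy = x$mean_years_on_initial_therapy
  )
}

#' Tidy a cost-effectiveness result
#'
#' `tidy()` returns the incremental outcomes as rows; for a probabilistic
#' result it returns the per-iteration scatter. `glance()` returns a
#' one-row summary.
#'
#' @param x A `ce_result`.
#' @param ... Unused.
#' @export
tidy.ce_result <- function(x, ...) {
  if (!is.null(x$scatter)) {
    return(tibble::as_tibble(x$scatter))
  }
  tibble::tibble(
    term = c("delta_qaly", "delta_cost", "delta_ly", "icer"),
    estimate = c(x$delta_qaly, x$delta_cost, x$delta_ly, x$icer)
  )
}

#' @rdname tidy.ce_result
#' @export
glance.ce_result <- function(x, ...) {
  tibble::tibble(
    intervention = x$intervention,
    comparator = x$comparator,
    delta_qaly = x$delta_qaly,
    delta_cost = x$delta_cost,
    icer = x$icer,
    dominance = x$dominance
  )
}

# ---- plots ------------------------------------------------------------------

#' Plot a cost-effectiveness result
#'
#' For a probabilistic result, draws the cost-effectiveness plane
#' (per-iteration incremental cost versus incremental QALYs) with the
#' deterministic point estimate; otherwise just the point estimate.
#'
#' @param object A `ce_result`.
#' @param wtp Willingness-to-pay threshold drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ce_result <- function(object, wtp = 30000, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Incremental QALYs",
      y = "Incremental cost",
      title = paste(object$intervention, "vs", object$comparator)
    )
  if (!is.null(object$scatter)) {
    p <- p + ggplot2::geom_point(
      data = object$scatter,
      ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost),
      alpha = 0.4, size = 0.8
    )
  }
  p + ggplot2::geom_point(
    data = tibble::tibble(delta_qaly = object$delta_qaly, delta_cost = object$delta_cost),
    ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost),
    colour = "red", size = 2
  )
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param ce A probabilistic `ce_result` (from [run_psa()]) or a CEAC
#'   tibble from [ceac_curve()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ce) {
  ceac <- if (inherits(ce, "ce_result")) ce$ceac else ce
  if (is.null(ceac)) t2d_argument_error("no CEAC available; run a probabilistic analysis")
  ggplot2::ggplot(ceac, ggplot2::aes(x = .data$wtp, y = .data$probability_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Willingness to pay per QALY", y = "P(cost-effective)")
}

#' @importFrom rlang .data
NULL
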