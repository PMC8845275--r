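# Sampling bounds: prevent non-physical draws. Fields absent here are
# sampled unbounded.
TRUNCATION_BOUNDS <- list(
  start_age = c(18, 100),
  duration = c(0, 50),
  hba1c = c(4, 15),
  sbp = c(80, 220),
  bmi = c(15, 70),
  total_cholesterol = c(50, 400),
  hdl = c(10, 120),
  egfr = c(10, 180)
)

# Mean and sd of a normal(mu, sigma) truncated to [a, b] (closed form).
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- pnorm(be) - pnorm(al)
  dphi <- dnorm(al) - dnorm(be)
  m <- mu + sigma * dphi / z
  v <- sigma^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / z - (dphi / z)^2)
  c(mean = m, sd = sqrt(pmax(v, 0)))
}

# Parent (mu, sigma) such that the [a, b]-truncated normal has the target
# mean/sd. Printed trial moments describe the realized distribution, so when
# truncation bites (e.g. diabetes duration bounded at 0) we solve for the
# parent rather than biasing the sampled moments.
truncnorm_match <- function(mean, sd, a, b) {
  if (sd == 0) return(c(mu = mean, sigma = 0))
  outside <- pnorm((a - mean) / sd) + pnorm((b - mean) / sd, lower.tail = FALSE)
  if (outside < 1e-6) return(c(mu = mean, sigma = sd))
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]), a, b)
    (mo[["mean"]] - mean)^2 + (mo[["sd"]] - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, control = list(reltol = 1e-14, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Inverse-CDF truncated-normal draw from pre-drawn uniforms (one uniform per
# value keeps random-number streams aligned across runs).
qtruncnorm <- function(u, mu, sigma, a, b) {
  if (sigma == 0) return(rep(mu, length(u)))
  pa <- pnorm(a, mu, sigma)
  pb <- pnorm(b, mu, sigma)
  qnorm(pa + u * (pb - pa), mu, sigma)
}

#' Generate a synthetic patient cohort
#'
#' Draws `n` independent patients from a [cohort_spec()]. Continuous
#' characteristics are sampled from truncated normal distributions whose
#' parent parameters are moment-matched so that the sampled (truncated)
#' distribution recovers the specified mean and sd; sex and smoking status
#' are independent Bernoulli draws. All complication flags start clear, the
#' therapy state starts at `"initial"`, and `baseline_bmi` records the
#' sampled BMI for later reversion on treatment intensification.
#'
#' @param spec A [cohort_spec()].
#' @param n Number of patients (>= 1).
#' @param seed Integer seed; the same `(spec, n, seed)` triple yields a
#'   bitwise-identical cohort.
#'
#' @return A tibble with one row per patient.
#' @export
sample_cohort <- function(spec, n, seed = 1L) {
  if (!inherits(spec, "cohort_spec")) t2d_argument_error("`spec` must be a cohort_spec")
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    t2d_argument_error("`n` must be a positive integer")
  }
  n <- as.integer(n)
  draw_cont <- function(field) {
    p <- spec[[field]]
    bounds <- TRUNCATION_BOUNDS[[field]] %||% c(-Inf, Inf)
    par <- truncnorm_match(p$mean, p$sd, bounds[1], bounds[2])
    qtruncnorm(runif(n), par[["mu"]], par[["sigma"]], bounds[1], bounds[2])
  }
  with_seed(seed, {
    # fixed draw order so the stream is reproducible column by column
    age <- draw_cont("start_age")
    duration <- draw_cont("duration")
    sex <- ifelse(runif(n) < spec$proportion_male, "male", "female")
    hba1c <- draw_cont("hba1c")
    sbp <- draw_cont("sbp")
    bmi <- draw_cont("bmi")
    tc <- draw_cont("total_cholesterol")
    hdl <- draw_cont("hdl")
    egfr <- draw_cont("egfr")
    smoker <- runif(n) < spec$proportion_smoker
    tibble::tibble(
      id = seq_len(n),
      age = age, sex = sex, duration = duration,
      hba1c = hba1c, sbp = sbp, tc = tc, hdl = hdl,
      bmi = bmi, egfr = egfr,
      smoker = smoker,
      cigarettes_per_day = ifelse(smoker, spec$cigarettes_per_day, 0L),
      alcohol_oz_per_week = spec$alcohol_oz_per_week,
      baseline_bmi = bmi,
      mi_history = FALSE, angina = FALSE, chf = FALSE,
      stroke_history = FALSE, pvd = FALSE,
      nephropathy_stage = "none",
      retinopathy_stage = "none",
      macular_edema = FALSE, cataract = FALSE, neuropathy = FALSE,
      foot_stage = "none",
      therapy = "initial",
      years_on_therapy = 0,
      alive = TRUE
    )
  })
}

#' Write a cohort to CSV
#'
#' One row per patient, columns in the order produced by [sample_cohort()].
#'
#' @param cohort A cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
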