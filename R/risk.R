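#' Parameterized risk equation
#'
#' A single complication or mortality equation. Three functional forms are
#' supported: Weibull proportional hazards on diabetes duration
#' (`"weibull_ph"`), logistic (`"logistic"`) and a constant annual hazard
#' (`"constant_rate"`). The linear predictor is
#' `L = intercept + sum(coef * (covariate - center))`; for the Weibull form
#' the cumulative hazard is `H(t) = exp(L) * t^shape` with `t` the diabetes
#' duration, and the annual event probability is
#' `1 - exp(-(H(t + 1) - H(t)))`.
#'
#' @param outcome Event tag (e.g. `"mi"`).
#' @param form `"weibull_ph"`, `"logistic"` or `"constant_rate"`.
#' @param intercept Log-hazard (Weibull/constant) or log-odds (logistic).
#' @param shape Weibull shape (> 0); ignored by other forms.
#' @param coefficients Named numeric vector of slopes per covariate tag.
#' @param centering Named numeric vector of covariate reference values
#'   (default 0 for tags not listed).
#' @param condition Optional covariate tag; the equation applies only to
#'   patients for whom the tag is nonzero (used for post-event excess
#'   mortality).
#' @param source_label Free-text provenance label.
#'
#' @return An object of class `risk_equation`.
#' @export
risk_equation <- function(outcome,
                          form = c("weibull_ph", "logistic", "constant_rate"),
                          intercept = 0,
                          shape = 1,
                          coefficients = numeric(),
                          centering = numeric(),
                          condition = NULL,
                          source_label = "") {
  form <- match.arg(form)
  if (form == "weibull_ph" && (!is.numeric(shape) || shape <= 0)) {
    t2d_validation_error("shape", "Weibull shape must be > 0")
  }
  structure(list(
    outcome = as.character(outcome),
    form = form,
    intercept = as.numeric(intercept),
    shape = as.numeric(shape),
    coefficients = coefficients,
    centering = centering,
    condition = condition,
    source_label = source_label
  ), class = "risk_equation")
}

# Covariate tags resolvable against a patient table. Derived tags:
# male/female/smoker indicators, age at diagnosis, total:HDL cholesterol
# ratio, complication-history indicators, ESRD and amputation indicators.
covariate_value <- function(tag, patients) {
  direct <- c(
    "age", "duration", "hba1c", "sbp", "tc", "hdl", "bmi", "egfr",
    "cigarettes_per_day", "alcohol_oz_per_week"
  )
  flags <- c(
    "mi_history", "stroke_history", "chf", "angina", "pvd",
    "neuropathy", "macular_edema", "cataract"
  )
  if (tag %in% direct) {
    v <- patients[[tag]]
    if (is.null(v)) t2d_config_error(paste0("missing covariate '", tag, "' in patient table"))
    return(as.numeric(v))
  }
  if (tag %in% flags) {
    v <- patients[[tag]]
    if (is.null(v)) t2d_config_error(paste0("missing covariate '", tag, "' in patient table"))
    return(as.numeric(v))
  }
  switch(tag,
    male = as.numeric(patients$sex == "male"),
    female = as.numeric(patients$sex == "female"),
    smoker = as.numeric(patients$smoker),
    age_diag = as.numeric(patients$age - patients$duration),
    tc_hdl_ratio = as.numeric(patients$tc / patients$hdl),
    esrd = as.numeric(patients$nephropathy_stage %in% ESRD_STAGES),
    amputated = as.numeric(patients$foot_stage == "amputated"),
    t2d_config_error(paste0("unknown covariate tag '", tag, "'"))
  )
}

linear_predictor <- function(eq, patients) {
  L <- rep(eq$intercept, nrow(patients))
  for (tag in names(eq$coefficients)) {
    center <- if (tag %in% names(eq$centering)) eq$centering[[tag]] else 0
    L <- L + eq$coefficients[[tag]] * (covariate_value(tag, patients) - center)
  }
  L
}

#' Annual event probability from a risk equation
#'
#' Evaluates a [risk_equation()] for each patient row and returns the
#' probability of the event occurring within the next annual cycle.
#'
#' @param patients Patient data frame (rows as produced by
#'   [sample_cohort()]).
#' @param eq A [risk_equation()].
#' @return Numeric vector of probabilities in `[0, 1]`, one per patient.
#' @export
annual_event_probability <- function(patients, eq) {
  if (!inherits(eq, "risk_equation")) t2d_argument_error("`eq` must be a risk_equation")
  L <- linear_predictor(eq, patients)
  p <- switch(eq$form,
    weibull_ph = {
      t <- pmax(as.numeric(patients$duration), 0)
      lam <- exp(L)
      1 - exp(-(lam * (t + 1)^eq$shape - lam * t^eq$shape))
    },
    logistic = plogis(L),
    constant_rate = 1 - exp(-exp(L))
  )
  pmin(pmax(p, 0), 1)
}

#' Annual probability of death
#'
#' Combines background mortality (life-table lookup by age and sex), acute
#' event case fatality for each event occurring this cycle, and conditional
#' post-event excess-mortality equations as independent competing risks:
#' `1 - prod(1 - q_i)`, capped at 1.
#'
#' @param patients Patient data frame.
#' @param life_table A [life_table()].
#' @param mortality_eqs List of [risk_equation()]s; an equation with a
#'   `condition` tag contributes only for patients for whom the tag is
#'   nonzero.
#' @param events List of character vectors (one per patient) of event tags
#'   that occurred this cycle; defaults to the `events` list-column of
#'   `patients`, else no events.
#' @param fatality Named numeric vector of acute case-fatality
#'   probabilities by event tag.
#'
#' @return Numeric vector of death probabilities in `[0, 1]`.
#' @export
annual_death_probability <- function(patients, life_table,
                                     mortality_eqs = list(),
                                     events = NULL,
                                     fatality = numeric()) {
  n <- nrow(patients)
  events <- events %||% patients[["events"]] %||% rep(list(character()), n)
  surv <- 1 - background_mortality(patients$age, patients$sex, life_table)
  if (length(fatality)) {
    for (tag in names(fatality)) {
      hit <- vapply(events, function(e) tag %in% e, logical(1))
      surv <- surv * ifelse(hit, 1 - fatality[[tag]], 1)
    }
  }
  for (eq in mortality_eqs) {
    q <- annual_event_probability(patients, eq)
    if (!is.null(eq$condition)) {
      q <- q * (covariate_value(eq$condition, patients) > 0)
    }
    surv <- surv * (1 - q)
  }
  pmin(pmax(1 - surv, 0), 1)
}

# ---- transition tables ------------------------------------------------------

#' Microvascular stage-transition table
#'
#' An ordered chain of health states with annual forward-transition
#' probabilities between adjacent stages, optionally modified by glycemic
#' control via a relative risk per %-point of HbA1c above 7%:
#' `p_eff = min(1, p * hba1c_rr^(HbA1c - 7))`.
#'
#' @param chain Chain name (the patient column it advances, e.g.
#'   `"retinopathy"`).
#' @param states Character vector of ordered stages, starting at `"none"`.
#' @param p Numeric vector of annual transition probabilities, one per
#'   adjacent pair (`length(states) - 1`).
#' @param hba1c_rr Relative risk per %-point of HbA1c above 7.
#' @return An object of class `transition_table`.
#' @export
transition_table <- function(chain, states, p, hba1c_rr = 1) {
  if (length(p) != length(states) - 1) {
    t2d_validation_error("p", "needs one probability per adjacent stage pair")
  }
  if (any(p < 0 | p > 1)) t2d_validation_error("p", "probabilities must lie in [0, 1]")
  structure(list(
    chain = chain, states = states, p = as.numeric(p),
    hba1c_rr = as.numeric(hba1c_rr)
  ), class = "transition_table")
}

#' Packaged microvascular transition tables
#'
#' Simplified stand-in sub-models for retinopathy, nephropathy (through
#' end-stage renal disease modalities), macular edema, cataract, neuropathy
#' and foot-ulcer progression, each an ordered forward chain with
#' HbA1c-modified annual probabilities. Values are editable via the
#' packaged YAML file.
#'
#' @param path Optional path to a transitions YAML file.
#' @return Named list of [transition_table()]s.
#' @export
default_transition_tables <- function(path = NULL) {
  path <- path %||% system.file("extdata", "transitions.yaml", package = "t2dsim", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    x <- raw[[nm]]
    transition_table(nm, x$states, unlist(x$p), x$hba1c_rr %||% 1)
  })
  names(out) <- names(raw)
  out
}

# ---- risk catalogs ----------------------------------------------------------

parse_risk_equation <- function(outcome, x) {
  risk_equation(
    outcome = outcome,
    form = x$form,
    intercept = x$intercept,
    shape = x$shape %||% 1,
    coefficients = unlist(x$coefficients) %||% numeric(),
    centering = unlist(x$centering) %||% numeric(),
    condition = x$condition,
    source_label = x$source_label %||% ""
  )
}

#' Packaged complication and mortality risk-equation catalogs
#'
#' Loads one of the two shipped equation sets (`"ukpds68"` base case,
#' `"ukpds82"` alternative). The equations follow the published UKPDS
#' outcome-equation forms (Weibull proportional hazards on diabetes
#' duration plus logistic/constant-rate forms); the shipped coefficient
#' values are editable data, not reproductions of the original
#' publications, and every test of the engine is written against the
#' functional forms.
#'
#' @param set `"ukpds68"` or `"ukpds82"`.
#' @param path Optional path to a risk-catalog YAML file.
#' @return A list of class `risk_catalog` with elements `label`, `events`
#'   (named list of [risk_equation()]s), `event_fatality` (named numeric)
#'   and `mortality` (list of conditional excess [risk_equation()]s).
#' @export
default_risk_coefficients <- function(set = c("ukpds68", "ukpds82"), path = NULL) {
  if (is.null(path)) {
    set <- match.arg(set)
    path <- system.file("extdata", paste0("risk_", set, ".yaml"), package = "t2dsim", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  events <- lapply(names(raw$events), function(nm) parse_risk_equation(nm, raw$events[[nm]]))
  names(events) <- names(raw$events)
  mortality <- lapply(names(raw$mortality %||% list()), function(nm) {
    parse_risk_equation(nm, raw$mortality[[nm]])
  })
  names(mortality) <- names(raw$mortality %||% list())
  structure(list(
    label = raw$label %||% "risk catalog",
    events = events,
    event_fatality = unlist(raw$event_fatality) %||% numeric(),
    mortality = mortality
  ), class = "risk_catalog")
}

# ---- cycle event sampling ---------------------------------------------------

advance_chain <- function(stage, chain, hba1c, u, frozen = NULL) {
  idx <- match(stage, chain$states)
  k <- length(chain$states)
  can <- !is.na(idx) & idx < k
  p <- ifelse(can, chain$p[pmin(idx, k - 1)], 0)
  p <- pmin(p * chain$hba1c_rr^(hba1c - 7), 1)
  if (!is.null(frozen)) p[frozen] <- 0
  adv <- u < p & can
  stage[adv] <- chain$states[idx[adv] + 1]
  stage
}

#' Draw one annual cycle of complication events
#'
#' Advances the complication sub-models for one cycle: acute/macrovascular
#' events are drawn from the catalog's risk equations in a fixed documented
#' order (MI, stroke, CHF, angina, PVD, renal failure, amputation), the
#' microvascular chains then advance at most one stage each, and
#' hypoglycemic event counts are drawn from Poisson distributions at the
#' supplied annual rates (split into nocturnal/daytime binomially). MI and
#' stroke may recur in later cycles; CHF, angina and PVD are first-ever
#' draws; each acute event occurs at most once per cycle. Dead patients are
#' never modified, but the random-number stream consumes the same number of
#' draws regardless of state so that runs stay aligned across arms and
#' scenarios.
#'
#' @param patients Patient data frame (needs an `alive` column).
#' @param risk A `risk_catalog` from [default_risk_coefficients()].
#' @param transitions Named list of [transition_table()]s.
#' @param nonsevere_rate,severe_rate Annual hypoglycemia rates (events per
#'   patient-year), length 1 or one per patient.
#' @param nocturnal_fraction_nonsevere,nocturnal_fraction_severe Fractions
#'   of hypoglycemic events occurring nocturnally.
#'
#' @return The patient tibble with updated complication stages/flags, an
#'   `events` list-column of this cycle's event tags, and hypoglycemia
#'   count columns `hypo_ns_day`, `hypo_ns_noct`, `hypo_sev_day`,
#'   `hypo_sev_noct`.
#' @export
sample_cycle_events <- function(patients, risk, transitions,
                                nonsevere_rate = 0, severe_rate = 0,
                                nocturnal_fraction_nonsevere = 0,
                                nocturnal_fraction_severe = 0) {
  n <- nrow(patients)
  alive <- patients$alive
  events <- rep(list(character()), n)
  add_event <- function(tag, hit) {
    for (i in which(hit)) events[[i]] <<- c(events[[i]], tag)
    events
  }

  for (tag in EVENT_ORDER) {
    u <- runif(n) # always consume one uniform per equation
    eq <- risk$events[[tag]]
    if (is.null(eq)) next
    p <- annual_event_probability(patients, eq)
    eligible <- switch(tag,
      mi = alive,
      stroke = alive,
      chf = alive & !patients$chf,
      angina = alive & !patients$angina,
      pvd = alive & !patients$pvd,
      renal_failure = alive &
        match(patients$nephropathy_stage, NEPHROPATHY_STAGES) <
          match("esrd_hemodialysis", NEPHROPATHY_STAGES),
      amputation = alive & patients$foot_stage != "amputated"
    )
    hit <- eligible & u < p
    if (any(hit)) {
      events <- add_event(tag, hit)
      switch(tag,
        mi = patients$mi_history[hit] <- TRUE,
        stroke = patients$stroke_history[hit] <- TRUE,
        chf = patients$chf[hit] <- TRUE,
        angina = patients$angina[hit] <- TRUE,
        pvd = patients$pvd[hit] <- TRUE,
        renal_failure = patients$nephropathy_stage[hit] <- "esrd_hemodialysis",
        amputation = patients$foot_stage[hit] <- "amputated"
      )
    }
  }

  had_renal_event <- vapply(events, function(e) "renal_failure" %in% e, logical(1))
  had_amputation <- vapply(events, function(e) "amputation" %in% e, logical(1))

  for (nm in c("retinopathy", "nephropathy", "macular_edema", "cataract", "neuropathy", "foot")) {
    u <- runif(n)
    tab <- transitions[[nm]]
    if (is.null(tab)) next
    hba1c <- patients$hba1c
    dead_or_na <- !alive
    switch(nm,
      retinopathy = {
        s <- advance_chain(patients$retinopathy_stage, tab, hba1c, u, frozen = dead_or_na)
        patients$retinopathy_stage <- s
      },
      nephropathy = {
        s <- advance_chain(patients$nephropathy_stage, tab, hba1c, u,
          frozen = dead_or_na | had_renal_event
        )
        patients$nephropathy_stage <- s
      },
      macular_edema = {
        s0 <- ifelse(patients$macular_edema, "macular_edema", "none")
        s <- advance_chain(s0, tab, hba1c, u, frozen = dead_or_na)
        patients$macular_edema <- s == "macular_edema"
      },
      cataract = {
        s0 <- ifelse(patients$cataract, "cataract", "none")
        s <- advance_chain(s0, tab, hba1c, u, frozen = dead_or_na)
        patients$cataract <- s == "cataract"
      },
      neuropathy = {
        s0 <- ifelse(patients$neuropathy, "neuropathy", "none")
        s <- advance_chain(s0, tab, hba1c, u, frozen = dead_or_na)
        patients$neuropathy <- s == "neuropathy"
      },
      foot = {
        s <- advance_chain(patients$foot_stage, tab, hba1c, u,
          frozen = dead_or_na | had_amputation
        )
        patients$foot_stage <- s
      }
    )
  }

  # Hypoglycemia: Poisson counts via quantile inversion (one uniform each),
  # nocturnal split binomial.
  lam_ns <- rep(nonsevere_rate, length.out = n) * alive
  lam_sev <- rep(severe_rate, length.out = n) * alive
  ns <- qpois(runif(n), lam_ns)
  sev <- qpois(runif(n), lam_sev)
  ns_noct <- qbinom(runif(n), ns, rep(nocturnal_fraction_nonsevere, length.out = n))
  sev_noct <- qbinom(runif(n), sev, rep(nocturnal_fraction_severe, length.out = n))

  patients$events <- events
  patients$hypo_ns_day <- ns - ns_noct
  patients$hypo_ns_noct <- ns_noct
  patients$hypo_sev_day <- sev - sev_noct
  patients$hypo_sev_noct <- sev_noct
  tibble::as_tibble(patients)
}
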