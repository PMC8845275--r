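Package: t2dsim
Title: Patient-Level Type 2 Diabetes Microsimulation for Cost-Effectiveness Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A patient-level (first-order Monte Carlo) microsimulation of
    long-term outcomes in type 2 diabetes, built for lifetime
    cost-effectiveness analysis of glucose-lowering therapies. Generates
    synthetic trial cohorts from published baseline characteristics, applies
    first-year treatment effects and UKPDS-style risk-factor progression with
    treatment intensification to basal insulin, simulates macrovascular and
    microvascular complications and mortality from editable Weibull
    proportional-hazards risk-equation catalogs, accumulates discounted
    quality-adjusted life years and costs, and computes incremental
    cost-effectiveness ratios, probabilistic sensitivity analyses
    (second-order Monte Carlo with cost-effectiveness acceptability curves)
    and a deterministic scenario suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
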