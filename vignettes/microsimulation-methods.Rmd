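---
title: "Model and methods: a patient-level type 2 diabetes cost-effectiveness microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dsim)
```

## What the model does

`t2dsim` is an annual-cycle, patient-level (first-order Monte Carlo)
simulation of long-term outcomes in type 2 diabetes, built to compare the
lifetime cost-effectiveness of glucose-lowering therapies. Two packaged
comparisons are shipped: oral semaglutide 14 mg versus empagliflozin 25 mg
(head-to-head trial data) and oral semaglutide 14 mg versus dulaglutide
1.5 mg (network meta-analysis effects on a second trial's baseline
cohort). Each simulated patient carries demographics, glycemic control
(HbA1c), blood pressure, lipids, BMI, eGFR, smoking status, a panel of
complication states, and a therapy state. A comparison pushes the *same*
sampled cohort through both treatment arms under common random numbers and
reports discounted life expectancy, quality-adjusted life expectancy
(QALYs), discounted costs by category, the incremental cost-effectiveness
ratio (ICER), probabilistic uncertainty (second-order Monte Carlo with
cost-effectiveness acceptability curves) and a deterministic scenario
suite.

The annual cycle, in fixed order:

1. **Risk-factor update.** Cycle 1 applies the arm's published first-year
   changes from baseline. From cycle 2, HbA1c follows the progression law,
   and blood pressure and lipids drift autoregressively toward attractors.
2. **Pending intensification** from the previous cycle's trigger takes
   effect: therapy becomes basal insulin, HbA1c falls per the
   intensification policy, BMI reverts to baseline (base case).
3. **Complication draws**, in a fixed documented order: myocardial
   infarction (MI), stroke, congestive heart failure, angina, peripheral
   vascular disease, renal failure, amputation from Weibull
   proportional-hazards equations; then the microvascular chains
   (retinopathy, nephropathy, macular edema, cataract, neuropathy, foot
   ulcer); then Poisson hypoglycemia counts. At most one occurrence per
   acute event type per cycle; MI and stroke may recur in later cycles.
4. **Intensification trigger**: a patient on initial therapy whose
   end-of-cycle HbA1c *strictly* exceeds 7.5% switches at the start of the
   next cycle. The basal-insulin state is absorbing.
5. **Utility and cost accrual** for the cycle (details below).
6. **Mortality**: background life-table probability, acute case fatality
   for this cycle's events, and conditional post-event excess mortality
   combine as independent competing risks, `1 - prod(1 - q_i)`.

Post-event utility and cost states ("post-MI", "post-stroke") begin the
cycle after the event; the event cycle itself carries the one-off event
disutility and event cost. Dead patients accrue nothing further.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| Horizon | 50 | years | captures remaining lifetime from a late-50s start age |
| Discount rates (costs, effects) | 0.04, 0.04 | /year | national guideline convention for the setting studied |
| Switch threshold | 7.5 | % HbA1c | loss of glycemic control on initial therapy |
| HbA1c law | autoregressive | — | see calibration below |
| Basal-insulin hypoglycemia | 4.08 / 0.10 | events/patient-year | published post-intensification rates |
| Basal insulin dose | 40 IU + 1 needle + 1 SMBG strip | /day | defined daily dose and stated resource use |
| Days per year | 365.25 | — | documented annualization constant |

## The HbA1c progression law and its calibration

After the first year, HbA1c follows

\[ A_{t+1} = w A_t + (1 - w)\,(a + b\,d_t), \]

with weight `w = 0.85` on the previous value, attractor intercept
`a = 9.5`%, and attractor slope `b = 0` per year of diabetes duration
`d_t`. Two properties motivate this form: HbA1c increases monotonically
whenever it sits below the attractor (progressive loss of glycemic
control), and between-arm differences decay geometrically at rate `w`
(treatment-arm convergence). The published description of the original
engine states the *outcome* of its progression equation — initial
therapies lasting 3 years (oral semaglutide, dulaglutide) and 2 years
(empagliflozin) — but not the equation itself, so the law's defaults were
chosen, before any simulation, by a normal-approximation argument: with
the printed baselines and first-year effects, per-patient switch-time
distributions under these defaults have means of roughly 2.4, 3.2, 2.9
and 3.3 years for the empagliflozin, semaglutide (trial), dulaglutide and
semaglutide (NMA) arms, which round to the published 2/3/3/3. The
simulation reproduces those rounded durations at `n = 10,000`.

The intensification response (`willis_linear`) applies an HbA1c drop of
`max(0, -1.20 + 0.30 * HbA1c)`; the original multivariate-equation
coefficients are not published, so these are editable defaults, and the
alternative policies `target_value` (set HbA1c to 7.0%) and `none` are
exact implementations of the published sensitivity analyses.

## Risk equations and the microvascular chains

Acute and macrovascular events use the UKPDS outcome-equation *form*:
linear predictor `L = intercept + sum(coef * (x - center))`, cumulative
hazard `H(t) = exp(L) * t^shape` on diabetes duration `t`, annual
probability `1 - exp(-(H(t+1) - H(t)))`. Logistic and constant-rate forms
are also supported. The shipped coefficient values
(`inst/extdata/risk_ukpds68.yaml`, `risk_ukpds82.yaml`) are editable
defaults in that form — plausible hazards and risk-factor gradients — not
reproductions of the cited publications, whose exact covariate sets for
the proprietary engine are undisclosed. They are the user-visible control
surface: swapping the catalog swaps the coefficients while the engine
code path is unchanged (a property the tests assert). Every engine test
is written against the functional forms with hand-set fixtures, so the
suite does not depend on the shipped values.

Microvascular disease progresses along ordered forward chains
(retinopathy none → background → proliferative → severe vision loss;
nephropathy none → microalbuminuria → gross proteinuria → hemodialysis →
peritoneal dialysis → transplant; a three-stage foot chain) with annual
probabilities multiplied by `rr^(HbA1c - 7)`. These are simplified
stand-in sub-models, shipped as editable data, whose role is to make
every chronic health state in the utility and cost catalogs reachable
with plausible incidence; they are not estimates of any published
transition matrix. Stages never regress; amputation (drawn from its own
event equation) may jump the foot chain forward to its terminal stage.

Background mortality uses a synthetic age–sex life table
(`life_table_synthetic.csv`, five-year bands to age 105, beyond which the
annual probability is 1) emulating a Southern-European schedule; replace
it with a national table for applied work.

## Utilities and costs

Utilities follow the published catalog: baseline 0.785 for uncomplicated
type 2 diabetes; each active chronic state subtracts
`0.785 - state utility` (additive decrements, floored at 0 — the
published catalog is itself constructed additively, and no combination
rule for multimorbidity is stated, so additivity is the model's
documented choice); one-off event decrements (MI 0.055, stroke 0.164,
amputation 0.280); per-event hypoglycemia decrements by severity and time
of day; and 0.0061 per BMI unit above 25 kg/m². Alternative models used in
scenarios: a flatter BMI slope, alternative constant hypoglycemia
decrements, and a diminishing model in which the *i*-th lifetime event of
a severity class carries `d * 0.8^(i-1)` (the original's functional form
is unpublished; this geometric form and its ratio are editable).

Costs are split into treatment, management, hypoglycemia, cardiovascular,
renal, ophthalmic and neuropathy/foot categories. The shipped catalog is
a **placeholder**: the original analysis priced resource use with national
tariffs that are not printed in the publication, so
`make_placeholder_cost_catalog()` provides a complete, linearly scalable
schema with plausible relative magnitudes. Absolute cost outputs (and
hence ICERs) are therefore only meaningful after the user substitutes
real tariffs; incremental *structure* (which categories move, in which
direction) is meaningful as shipped.

**Death-cycle accrual**: a patient dying in cycle `t` accrues half a
cycle of state utility, life-years and recurring (therapy, management,
state) costs, plus full event costs and disutilities; switchable to
full-cycle. **Discounting** divides cycle `t` by `(1 + r)^(t-1)` — the
first year undiscounted — fixed for reproducibility since the original
convention is unstated.

## Random numbers and reproducibility

All stochastic draws go through quantile inversion (`qnorm`, `qpois`,
`qbinom`) of `runif` streams, and the engine consumes an identical number
of uniforms per cycle regardless of patient state. Consequences: the same
seed gives bitwise-identical runs; both arms of a comparison consume the
same baseline cohort (seed) and the same event-draw stream (seed + 1), so
identical profiles give exactly zero incremental outcomes, and scenario
runs differ from the base case only through the parameters changed.
Second-order (PSA) parameter draws use per-iteration seeds
(seed + 100000 + i) with first-order streams at seed + i.

Cohort sampling draws each characteristic independently (no correlation
structure is published) from truncated normals — age in [18, 100], HbA1c
[4, 15], BMI [15, 70], SBP [80, 220], duration [0, 50] — whose *parent*
parameters are moment-matched so the truncated distribution reproduces
the printed mean and sd exactly; without this, truncating diabetes
duration (mean 7, sd 6.09) at zero would inflate its sampled mean by more
than a year. Proportions (sex, smoking) are Bernoulli draws;
cigarettes/day is carried as an integer constant.

## The probabilistic analysis

Per iteration: treatment-effect means are drawn from normal distributions
with their published standard errors; complication cost entries from
gamma distributions with coefficient of variation 0.2 (mean-preserving);
utility decrements from scaled beta distributions with sd equal to 10% of
the decrement. The named quantities are those the original reports
sampling; the distribution families and spreads for costs and utilities
are this package's documented defaults (exposed as arguments) since the
original does not state them. Default dimensions are 500 first-order
patients × as many iterations as requested; the original's PSA dimensions
are unreported.

## What the synthetic data does and does not emulate

The cohort generator reproduces the printed baseline *moments* and the
first-year effect sizes; it does not emulate baseline correlations
(unpublished), within-trial dropout, estimand construction, or any
cardiovascular-outcome-trial effects (deliberately excluded from the
original analysis). Passing tests therefore demonstrate that the engine's
dynamics, accounting and comparative statics are correct under the stated
conditions — not that absolute projections match any real population.
Known further limitations: one treatment pathway only (initial therapy →
basal insulin), annual resolution, no therapy adherence or persistence
modelling, and placeholder absolute costs.

## Problem sizes

Calibration and input-recovery checks run at 10,000 patients (the
package's reference first-order size); directional scenario checks at
6,000 with common seeds; structural property tests at 100–300 patients
where the property is exact (common-random-number zeros, accrual
arithmetic, monotonicity). The scenario-suite coverage test uses small
cohorts because it checks table structure, not magnitudes.

## Worked example

```{r example, eval = FALSE}
study <- load_study_config("pioneer2")
rc <- run_comparison(study, n_patients = 10000, seed = 1)
glance(rc$ce)
tidy(rc$arms$oral_semaglutide)
autoplot(rc$ce)

psa <- run_psa(study, n_iterations = 500, n_patients = 500, seed = 1)
plot_ceac(psa)

run_scenario_suite(study, n_patients = 2000, seed = 1)
```
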