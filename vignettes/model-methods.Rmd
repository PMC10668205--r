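---
title: "Model methods: structure, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods: structure, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htnce)
```

## The decision problem

`htnce` implements a decision-analytic model comparing two strategies for
young and middle-aged (< 60 years) stage 1 hypertensive patients
(130--139 / 80--89 mm Hg) at high cardiovascular risk: antihypertensive
**drug treatment** versus **non-drug management**. The model projects
discounted quality-adjusted life years (QALYs) and discounted societal
costs per patient, and summarises the comparison as an incremental
cost-effectiveness ratio (ICER) or a dominance verdict, judged against a
willingness-to-pay (WTP) anchor of one per-capita GDP ($10,438.66 in
2020 US dollars).

## Model structure

Seven clinical health states: stage 1 hypertension, stage 2 hypertension,
stroke, post-stroke, myocardial infarction (MI), post-MI, and death.
Everyone starts in stage 1 hypertension. Per annual cycle, stage 1
patients may stay, progress to stage 2, suffer a first stroke or MI, or
die; stage 2 patients may stay, suffer a first event, or die; patients
with an event history face recurrent events, cross events (MI after
stroke, stroke after MI), and post-event mortality. Death is absorbing.
Acute stroke and MI are one-cycle *tunnel* states: absent recurrence or
death, the patient moves to the matching chronic post-event state after
one cycle. A recurrent event re-enters the acute state and re-incurs the
first-year event cost.

Because second-event rates are stratified by hypertension stage, the
engine expands each event-history state over a persistent *stage
attribute* frozen at the time of the first event: a patient who strokes
out of stage 1 keeps using the stage 1 second-event column, a patient who
strokes out of stage 2 the stage 2 column. There is no progression after
a first event. This gives 11 engine states in total.

Two matched evaluators share all accrual conventions:

* `solve_cohort()` propagates the full occupancy distribution — the
  deterministic expected value, exact up to floating point;
* `run_microsimulation()` simulates individual trajectories
  (first-order Monte Carlo) and reports means with Monte-Carlo standard
  errors.

The cohort solver is the expectation of the microsimulation over the same
state space, which the test suite verifies on perturbed parameter sets
(means within 4 Monte-Carlo SEs at 100,000 individuals).

## From rates to transition probabilities

All event inputs are rates per 1000 person-years. Each cause-specific
rate becomes a hazard $h_i$; within a cycle the total exit probability is
$1 - e^{-\sum h_i}$, split across destinations proportionally to the
hazards. This is exact under constant competing hazards, keeps every row
of the transition matrix a probability distribution for any inputs, and
never needs truncation. Treatment effects multiply hazards (not
probabilities), the standard reading of relative risks from trial
meta-analyses.

The printed annual progression frequency (24.08%) is used directly as an
annual probability, converted to a hazard only for the competing-risk
allocation.

## Treatment effects: two deliberate structural choices

Two mechanics of the published model are not stated explicitly; both are
exposed as options on `run_config()` and both defaults were chosen so the
model reproduces the published per-arm results tables, not just their
direction.

**The progression effect is a risk reduction, not a hazard ratio
(`progression_effect = "risk_reduction"`).** The treatment-effect table
prints 0.61 (0.53--0.70) for hypertension progression, and the
surrounding text calls these effects "RR reductions". Applied as a hazard
multiplier, the drug arm's stage 1 occupancy — and with it the stage 1
cost category — comes out roughly 28% below the published value and the
15-year incremental cost flips sign, contradicting the published
dominance verdict. Applied as a proportional risk reduction (treated
annual progression $0.2408 \times (1 - 0.61) = 0.0939$), the drug-arm
stage 1 cost lands within 4% of the published figure and dominance holds.
The trial literature on treating high-normal blood pressure reports
reductions of incident hypertension of this magnitude, which supports the
reduction reading. The hazard-ratio variant remains available
(`progression_effect = "hazard_ratio"`). Under the reduction reading the
neutral (no-effect) value of this parameter is 0, not 1, which is why the
parameter validator accepts a zero.

**Stage 2 treatment effects stay on after progression
(`stage2_effects = TRUE`).** Drug-arm patients who progress to stage 2
(and their post-event states) use the stage 2 column of the
treatment-effect table; non-drug patients never receive effects. With
these effects off, the drug arm's stroke and MI savings shrink well below
the published category changes and the 15-year dominance becomes a
knife-edge (incremental cost $-4$); with them on, the published direction
and approximate magnitude of every category change is reproduced.

Cross events and post-event mortality in the drug arm use the
first-event RR of the matching endpoint (MI after stroke uses the MI RR,
and so on). The rates involved are at most 1.4/1000, so this choice is
numerically negligible.

## Economics

Per-cycle accrual uses five cost categories (2020 US$ per year of state
occupancy):

| category | drug arm | non-drug arm |
|---|---|---|
| stage 1 | screening 28.71 + drug 88.92 | screening 28.71 |
| stage 2 | 28.71 + 88.92 | 28.71 + 88.92 (stage 2 implies medication) |
| stroke | 3249.55 acute, 1525.64 chronic | same |
| MI | 4710.83 acute, 428.26 chronic | same |
| productivity | 275.38 × (1 − 0.048) | 275.38 |

Productivity losses (early retirement) accrue to every living patient,
regardless of clinical state, during the first 10 years only — the
cohort's mean age (45.9) plus its average early-retirement span pins the
window — with a 4.8% arm-level reduction under treatment. QALYs multiply
state occupancy by the state utility (hypertension 0.90, stroke 0.63,
post-stroke 0.65, MI 0.76, post-MI 0.88, death 0).

**Discounting and half-cycle correction.** Both costs and QALYs discount
at 5%/year with factor $(1+d)^{-t}$, cycle 0 undiscounted. State
membership is valued at cycle boundaries $t = 0, \dots, H$ with
trapezoidal weights $(\tfrac12, 1, \dots, 1, \tfrac12)$ — the
conventional half-cycle correction. This convention was selected because
it reproduces the published non-drug column almost exactly (stage 1 cost
within $0.7, stage 2 within $2). With the correction off, membership
counts at cycle starts ($t = 0, \dots, H-1$, full weight), so the
zero-event, zero-discount QALY over $H$ cycles is exactly $H$. The
productivity window gets its own trapezoid over boundaries
$0, \dots, \min(10, H)$.

ICER and dominance classification follow the standard quadrant rules;
cost-effectiveness at a threshold $\lambda$ uses net monetary benefit
$\lambda \,\Delta E - \Delta C > 0$, which handles dominance and the
negative quadrants without division.

## Uncertainty analysis

**One-way (tornado).** Every rate and relative risk varies over its 95%
CI, costs over ±25%, utilities over their ranges, the discount rate over
0--8%. The ranking outcome is the incremental NMB at one GDP/QALY (the
ICER is reported per entry but is unstable where $\Delta E$ crosses 0).

**Probabilistic (PSA).** Each of 10,000 draws samples every uncertain
parameter: beta distributions for rates, the progression probability and
utilities (fitted so the mean is exact and the 2.5/97.5% quantiles match
the printed interval in least squares, via a one-dimensional search with
$\beta = \alpha(1-m)/m$); gamma for costs (method of moments, CV = 0.25);
lognormal for relative risks (median at the estimate,
$\sigma = \log(\mathrm{hi}/\mathrm{lo})/(2 \times 1.96)$). These families
respect the parameters' domains by construction, so no truncation is
applied. The inner evaluation is the deterministic cohort solver, so the
spread across draws is parameter (second-order) uncertainty only — the
conventional reading, and consistent in scale with the published PSA
standard deviations; an inner microsimulation is available as an option.
The CEAC reports, per WTP value, the fraction of draws with positive
incremental NMB, and Welch two-sample t tests summarise the per-draw cost
and QALY vectors.

## Synthetic upstream data

`generate_person_time()` emulates the statistical structure the rate
inputs assume: per endpoint, exponential event times at the generating
hazard, censored at a uniform follow-up time. The uniform interval
(1.90--14.56 years) is chosen to give the cohort's mean follow-up of 8.23
years within the reported range. `estimate_rate_ci()` recovers rates with
exact Poisson (Garwood) 95% CIs; property tests verify 3-SE recovery of
generating rates and 93--97% interval coverage. Retirement records
(`generate_retirement_records()`) carry sex-specific legal retirement
ages (60 men / 55 women) and gamma-distributed early-retirement spans
with mean 9.5 years; `productivity_loss()` is the early-retirement span
times the average wage. The generator does **not** emulate longitudinal
blood-pressure trajectories, within-person correlation between endpoints,
or the cohort's demographic composition — so passing recovery tests show
the estimators are correct for the assumed sampling structure, not that
the structure matches any real cohort.

## Numerical choices and degenerate inputs

* Beta fitting searches $\log\alpha \in [-7, 16]$ with `optimize()`
  (tolerance 1e-10); degenerate intervals (`lo == hi == mean`) become
  point masses, as do costs with a zero uncertainty range.
* Equal-effectiveness comparisons ($\Delta E = 0$) are flagged
  (`cost_comparison_only`) rather than divided.
* Monetary outputs are rounded to cents at CSV serialisation only;
  internal arithmetic and JSON keep full precision.
* Seeds: every stochastic entry point takes an explicit integer seed and
  is bit-reproducible under it.

## Known limitations

* **The published incremental QALYs are not reproducible from the
  published inputs.** The per-arm QALY and cost levels, the category
  decomposition, the PSA means, and the dominance verdicts all reproduce
  within a few percent, but the printed incremental QALYs (0.12 at 8
  years, 0.29 at 15 years) are ~4x and ~2.5x what the printed rates,
  effects and utilities can generate under any structural reading we
  tried; the model's incremental QALYs are ~0.031 and ~0.114. The
  published 8-year ICER ($188.50/QALY) is correspondingly smaller than
  this model's (~$3,100/QALY — still far below the 1-GDP threshold, so
  the qualitative conclusion is unchanged). Likewise, with productivity
  losses excluded the 15-year strategy stays cost-effective but is no
  longer strictly dominant here, while the published supplementary
  analysis reports consistency with the main (dominant) result.
* The printed post-event mortality rates (0.2--1.4/1000) are an order of
  magnitude below the printed hypertensive mortality (4.1--8.9/1000).
  The model uses the printed values verbatim; one side effect is that
  preventing an MI can *lose* a microscopic amount of QALYs (post-MI
  utility 0.88 with near-zero mortality), so QALY monotonicity in
  hazards holds only for stroke-, death- and progression-related inputs.
* No age- or sex-specific mortality, no time-varying hazards, no
  individual covariates beyond the stage attribute, no medication
  adherence, no absenteeism/presenteeism productivity components, and no
  currency/inflation machinery (inputs are already 2020 US$).

## Problem sizes used by the shipped analyses

The package's own analyses use the deterministic cohort solver for the
base case and scenarios (horizons 8, 15, 55), 10,000 draws for the PSA,
and 100,000 individuals where the microsimulation cross-check runs. The
test suite exercises the same code paths at these scales.

## A worked base case

```{r base-case, eval = FALSE}
params <- default_parameters()
bc <- base_case_table(params, run_config(horizon_years = 15))
bc$table
bc$comparison

psa <- run_psa(params, run_config(15), n_draws = 10000, seed = 1)
ceac(psa, c(10438.66, 31315.98))
```
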