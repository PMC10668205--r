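# htnce

Cost-effectiveness modelling of antihypertensive drug treatment for
young and middle-aged (< 60 years) stage 1 hypertensive patients
(130–139 / 80–89 mm Hg) at high cardiovascular risk.

Recent hypertension guidelines disagree on whether these patients should
receive drug therapy. `htnce` implements the decision model used to
weigh that choice from a societal perspective: a seven-state Markov
model (stage 1 hypertension, stage 2 hypertension, stroke, post-stroke,
MI, post-MI, death) run as an individual-level microsimulation with a
matched deterministic cohort solver, comparing **drug treatment**
against **non-drug management** over 8-, 15- and 55-year horizons.

Per annual cycle the model accrues discounted costs in five categories
(stage 1 care, stage 2 care, stroke, MI, and productivity losses from
early retirement, the latter limited to the first 10 years) and
discounted QALYs via health-state utilities, with a trapezoidal
half-cycle correction. The comparison is summarised as

> ICER = ΔCost / ΔQALY,

with dominance (`ΔC < 0`, `ΔE > 0`) reported in place of a ratio, and
cost-effectiveness at a willingness-to-pay threshold λ judged by net
monetary benefit `λ·ΔE − ΔC > 0` (λ is anchored at one per-capita GDP,
$10,438.66 in 2020 US$). Uncertainty is handled by one-way (tornado)
analyses and a 10,000-draw probabilistic sensitivity analysis — beta
distributions for rates, probabilities and utilities, gamma for costs,
lognormal for relative risks — summarised as a cost-effectiveness
acceptability curve (CEAC). A synthetic-cohort module generates
person-time event tables and retirement records with known parameters
and re-estimates the model inputs (exact Poisson rate CIs), closing the
loop from raw-data structure to parameter file.

All inputs live in a documented JSON parameter file; the shipped
base case is at
`system.file("extdata", "table1_base_case.json", package = "htnce")`.

## Worked example

```r
library(htnce)

params <- default_parameters()
bc <- base_case_table(params, run_config(horizon_years = 15))
bc$table
#> # A tibble: 7 × 4
#>   outcome                drug non_drug   change
#>   <chr>                 <dbl>    <dbl>    <dbl>
#> 1 discounted_qalys       9.21     9.09    0.114
#> 2 discounted_cost     3771.    3819.    -48.1
#> 3 cost_stage1          686.      86.5   599.
#> 4 cost_stage2          486.     791.   -304.
#> 5 cost_stroke          455.     676.   -222.
#> 6 cost_mi              112.     142.    -30.1
#> 7 cost_productivity   2032.    2123.    -91.2

bc$comparison
#> <ce_comparison> drug vs non_drug
#>   delta cost $-48.10, delta QALY 0.1136
#>   verdict: dominant (cost-saving); NMB at $10439/QALY = $1234.24 (cost-effective)
```

Over 15 years, drug treatment yields more QALYs (9.21 vs 9.09) at lower
total cost ($3771 vs $3819): the extra stage 1 treatment spending
(+$599) is more than offset by savings on stage 2 care, strokes, MIs and
productivity losses, so treatment *dominates*. Uncertainty:

```r
psa <- run_psa(params, run_config(15), n_draws = 10000, seed = 1)
ceac(psa, c(10438.66, 31315.98))
#> # A tibble: 2 × 2
#>      wtp prob_cost_effective
#>    <dbl>               <dbl>
#> 1 10439.                   1
#> 2 31316.                   1

plot_psa_scatter(psa)        # cost-effectiveness plane
plot_ceac(ceac(psa))         # acceptability curve
plot_tornado(one_way_tornado(params, run_config(15)))
```

Result objects are tibble-friendly (`tidy()`, `glance()`, `autoplot()`),
and `report_base_case()`, `report_psa()`, `report_tornado()`,
`report_scenarios()`, `report_synthetic()` write canonical CSV/JSON
result files with a run manifest. A thin command-line wrapper ships at
`system.file("cli", "htnce.R", package = "htnce")`.

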