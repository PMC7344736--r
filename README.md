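# markovcea

Markov cohort cost-effectiveness analysis in R, built around a four-state
model of one-year adjuvant trastuzumab versus chemotherapy alone in
HER2-positive early breast cancer.

## What this package is for

Health-economic evaluations of adjuvant cancer therapy commonly use a
discrete-time Markov cohort model: a closed cohort moves annually between the
health states *stable*, *recurrence*, *metastasis* and *death* (absorbing)
according to a row-stochastic transition matrix, and each strategy's
discounted costs and quality-adjusted life years (QALYs) are accumulated
along the cohort trace. `markovcea` implements that workflow end to end for
analysts who want a scriptable, testable alternative to spreadsheet or GUI
decision-tree tools:

- **Transition estimation** — maximum-likelihood row normalisation of
  observed transition count tables, plus direct entry of published (rounded)
  probabilities with controlled renormalisation.
- **Cohort engine** — trace recursion `x_{t+1} = x_t P`, trapezoidal
  half-cycle correction (weights ½ at cycles 0 and N, 1 elsewhere), separate
  cost/QALY discounting (base case 3 % per annual cycle), fixed 20-year or
  lifetime horizons.
- **Decision analysis** — incremental cost-effectiveness ratios
  (ICER = ΔC/ΔE), dominance and extended dominance, the efficiency frontier,
  and net monetary benefit (NMB = λ·E − C).
- **Sensitivity analysis** — one-way ±10 % tornado analysis over costs,
  utilities, discount rates and single transition probabilities;
  probabilistic sensitivity analysis drawing utilities from beta and
  strategy costs from gamma distributions (method of moments), with
  cost-effectiveness acceptability curves at €20,000/€40,000/€60,000 per
  QALY; ICER-versus-horizon sweeps.
- **Synthetic cohorts** — a patient-level history generator with the same
  multinomial transition structure and gamma cost components, so the whole
  estimation-to-decision pipeline can be validated without access to
  registry data.

The built-in case study (`trastuzumab_inputs()`) carries the published model
inputs of a real-world Cyprus NHS payer analysis: transition counts and
probabilities for a control arm (n = 30), a pooled trastuzumab arm (n = 148)
and three treatment subgroups (anthracyclines then trastuzumab, n = 38; no
anthracyclines, n = 14; anthracyclines + taxanes, n = 96); EQ-5D utilities
(stable 0.620, recurrence 0.767, metastasis 0.692); one-time treatment costs
per arm with standard deviations; and the published per-strategy QALY totals
used for ICER arithmetic.

## Worked example

```r
library(markovcea)
inp <- trastuzumab_inputs()

estimate_transition_matrix(inp$counts$control)
#> Transition matrix (estimated, arm: control)
#>            stable recurrence metastasis death
#> stable      0.744      0.038      0.115 0.103
#> recurrence  1.000      0.000      0.000 0.000
#> metastasis  1.000      0.000      0.000 0.000
#> death       0.000      0.000      0.000 1.000
```

Each row is the observed counts divided by the row total: of 78 recorded
annual transitions out of *stable* in the control arm, 8 ended in death
(8/78 ≈ 0.103). The estimated matrices, one-time treatment costs and EQ-5D
utilities combine into a model; its summary reports discounted totals,
pairwise increments against the reference arm, and the efficiency frontier:

```r
mod <- cea_model(trastuzumab_strategies(inp, arms = "subgroups"))
summary(mod)
#> Per-strategy discounted totals:
#>                          strategy     cost  qalys cycles
#>                           control  3978.18 4.6936     20
#>         anthracycline_trastuzumab 41308.19 9.4950     20
#>      no_anthracycline_trastuzumab 43664.83 9.6196     20
#>  anthracycline_taxane_trastuzumab 47304.25 8.7128     20
#>
#> Incremental vs reference:
#>                      intervention comparator delta_cost delta_qalys     icer  flag
#>         anthracycline_trastuzumab    control   37330.01      4.8014  7774.74 ratio
#>      no_anthracycline_trastuzumab    control   39686.65      4.9260  8056.55 ratio
#>  anthracycline_taxane_trastuzumab    control   43326.07      4.0192 10779.69 ratio
#>
#> Efficiency frontier:
#>                          strategy     cost  qalys    status                comparator     icer
#>                           control  3978.18 4.6936  frontier                      <NA>       NA
#>         anthracycline_trastuzumab 41308.19 9.4950  frontier                   control  7774.74
#>      no_anthracycline_trastuzumab 43664.83 9.6196  frontier anthracycline_trastuzumab 18919.70
#>  anthracycline_taxane_trastuzumab 47304.25 8.7128 dominated                      <NA>       NA
```

Costs equal each arm's one-time treatment cost (state occupancy carries no
further cost in the base case), so every extra model cycle adds QALYs but no
cost and the ICER falls as the horizon lengthens. The
anthracyclines + taxanes subgroup is dominated: it costs more and yields
fewer QALYs than the cheaper trastuzumab subgroups. Note the QALY totals are
the engine's own (certified against closed forms); they are larger than the
published totals, whose generating model is not fully documented — see the
methods vignette.

ICER arithmetic on the published totals themselves is a one-liner:

```r
icer(ce_result("control", 3978.18, 1.42),
     ce_result("anthracycline_trastuzumab", 41308.19, 3.46))
#> anthracycline_trastuzumab vs control: dCost 37330.01, dQALYs 2.0400 -> ICER 18299.02 EUR/QALY
```

which reproduces the published 20-year subgroup ICER (€18,301.55; the small
gap comes from the publication's 2-decimal QALY rounding). Sensitivity
analysis confirms the published finding that the result is driven by the
trastuzumab treatment cost and the stable-state utility:

```r
tornado(cea_model(trastuzumab_strategies(inp, arms = "pooled")))
#> One-way sensitivity analysis (tornado order)
#>         parameter    base      low     high   range
#>  cost.trastuzumab 9662.31  8603.33 10721.30 2117.97
#>    utility.stable 9662.31 10741.67  8780.07 1961.60
#>     discount.qaly 9662.31  9340.28  9992.29  652.01
#>  ...
```

`simulate(mod, nsim = 1000, seed = 1)` runs the probabilistic sensitivity
analysis and `ceac()` turns the draws into acceptability fractions. A thin
command-line shim (`inst/cli/markovcea`) exposes the pipeline as
subcommands (`estimate`, `run`, `icer`, `dsa`, `psa`, `horizon-sweep`,
`simulate`, `fixtures`); see `?cea_cli`.

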