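---
title: "Model and methods: Markov cohort cost-effectiveness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: Markov cohort cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `markovcea`, the choices
made where the published analysis left the method under-specified, and what
the package's validation does and does not establish.

## The cohort model

A closed cohort of unit mass moves between four health states — *stable*,
*recurrence*, *metastasis* and *death* — in annual cycles. Death is
absorbing. Writing $x_t$ for the row vector of state occupancy at cycle $t$
and $P$ for the row-stochastic transition matrix, the trace recursion is

$$x_{t+1} = x_t P, \qquad x_0 = (1, 0, 0, 0),$$

i.e. every patient starts in stable (post-surgery remission). Discounted
QALYs over a horizon of $N$ cycles are

$$E = \sum_{t=0}^{N} w_t \,(u \cdot x_t)\,(1+r)^{-t},$$

with per-state utility vector $u$, QALY discount rate $r$ (base case 3% per
cycle) and trapezoidal half-cycle weights $w_0 = w_N = \tfrac12$, $w_t = 1$
otherwise. The half-cycle correction is implemented as these trapezoidal
end-weights — the standard reading when a publication states that a
half-cycle correction was applied without further detail; it is exactly the
trapezoid rule applied to the discounted utility stream, and for an immortal
single-state cohort it reduces to a closed-form discounted annuity, which
the test suite checks to $10^{-12}$.

Costs are a single upfront amount per strategy, entered at cycle 0 and not
discounted. This follows from the published results themselves: the
per-strategy cost totals are identical at the 20-year and lifetime horizons,
which is only possible if no cost accrues with state occupancy. A per-state
annual cost hook exists (`state_cost` in `strategy()`) and is accumulated
like QALYs, with half-cycle weighting and the cost discount rate, but it is
zero in the base case.

### Parameters

| Parameter | Base value | Meaning |
|---|---|---|
| utilities (EQ-5D) | stable 0.620, recurrence 0.767, metastasis 0.692, death 0 | per-state quality weight per life-year |
| disutility deductions | −0.215 (stable/recurrence), −0.0519 (metastasis) | optional treatment-phase adjustments |
| discount rates | 3 % per annual cycle, costs and QALYs | present-value conversion |
| horizon | 20 cycles, or lifetime | analysis time frame |
| thresholds | €20,000 / €40,000 / €60,000 per QALY | willingness to pay |
| upfront costs | €3978.18 / €45,420.45 / €41,308.19 / €43,664.83 / €47,304.25 | per-arm one-time treatment cost |

The published recurrence utility (0.767) exceeds the stable utility (0.620).
We use the values as printed and do not reinterpret them; if the intent was
a treatment-year disutility inside "stable", that is what the deduction
parameters are for. The deductions are listed with the published inputs but
their mode of entry is not stated, so they default to **off**; they can be
applied to the first cycle only (`deduction_mode = "first_cycle"`, a one-off
treatment-phase decrement weighted by $w_0 = \tfrac12$) or to every cycle
(`"all_cycles"`). Death utility is 0 by QALY convention (not stated in the
source inputs). No background other-cause mortality is added, because none
appears in the published transition data.

### Transition matrices

`estimate_transition_matrix()` is the multinomial maximum-likelihood
estimator: each probability is the cell count divided by its row total.
Interval censoring, competing-risk corrections and hazard modelling are
deliberately out of scope — the source analysis used raw annual transition
frequencies, and the package reproduces exactly that estimator. One
transition record per patient-year is assumed. A non-absorbing row with no
observed transitions becomes a self-loop with a warning: this keeps the
chain well-defined without inventing mortality that the data do not
contain.

`transition_matrix()` accepts published, 3-decimal-rounded probabilities
directly. A row whose printed sum is within 0.01 of 1 is renormalised (the
published pooled-arm metastasis row prints 0.571/0.357/0.072, i.e. 1/14 was
nudged from 0.071 to 0.072 so the row sums to 1.000); larger deviations are
rejected as data errors. All computation runs at full precision;
probabilities are rounded to 3 decimals, money to 2, only at print/report
time.

### The lifetime horizon

"Lifetime" is operationalised as the smallest $N$ at which at least 99.9 %
of the cohort mass is in death ($\varepsilon = 0.001$), capped at 100
cycles; both knobs sit in `horizon_spec()`. Two of the published subgroup
matrices (anthracyclines-then-trastuzumab and no-anthracyclines) contain no
transition into death at all, so their cohorts never absorb; there the
engine runs to the cap and warns. Each strategy gets its own lifetime cycle
count, since the arms absorb at different rates.

## Decision rules

The pairwise comparison classifies $(\Delta C, \Delta E)$ before dividing:
*dominant* when the alternative is no costlier and more effective (or
cheaper and no less effective), *dominated* in the mirror case,
*equivalent* at exact equality, otherwise the ratio
$\mathrm{ICER} = \Delta C / \Delta E$. Zero QALY gain at a cost difference
is classified as dominance, never as an infinite ratio. When both deltas
are negative (cheaper, less effective — the south-west quadrant) the
positive ratio is reported and reads as cost saved per QALY forgone.

The multi-strategy frontier sorts by cost (ties broken by higher QALYs, for
deterministic output), removes weakly dominated strategies, then removes
extended-dominated strategies — those whose incremental ICER exceeds the
next frontier member's — iteratively. Exactly collinear strategies produce
equal sequential ICERs and the middle strategy is retained: removal uses a
strict comparison (with a $10^{-12}$ guard), so frontier ICERs are
nondecreasing, and strictly increasing off ties. The implementation is
tested against an exhaustive oracle that checks every strategy against
every convex combination of two others.

Net monetary benefit is $\lambda E - C$; for $\Delta E > 0$, $\Delta C > 0$
the alternative wins exactly when $\lambda$ exceeds the pairwise ICER, an
identity the suite checks on random instances.

## Sensitivity analysis

**One-way (tornado).** Each addressable parameter (strategy costs,
living-state utilities, discount rates, single transition probabilities) is
set to ±10 % of its base value, the model is rebuilt, and the pairwise ICER
recomputed; bars are sorted by range. A perturbed transition probability is
clamped to $[0,1]$ (with a warning) and its row renormalised, so the matrix
stays stochastic. With the case-study inputs the two widest bars are the
trastuzumab treatment cost and the stable-state utility, matching the
published finding.

**Probabilistic.** Per iteration, utilities are drawn from beta
distributions and strategy-level upfront costs from gamma distributions,
both parameterised by the method of moments: gamma shape $\mu^2/\sigma^2$
and scale $\sigma^2/\mu$; beta via $\alpha + \beta = \mu(1-\mu)/s^2 - 1$.
The source analysis names only the distribution families. Costs are sampled
at the strategy level with the published total-cost means and SDs (the
published cost breakdown goes no deeper), and transition probabilities are
held fixed, matching the published list of sampled quantities (a Dirichlet
row option was considered and left out as out of scope). Utility standard
errors are not published; the default is 10 % of the mean (shrunk if needed
to keep the beta feasible), overridable per state — an explicitly supplied
infeasible SE is an error naming the state. A zero SD makes the
distribution degenerate at its mean, so the PSA collapses to the base case,
which the tests exploit. The base case uses 1000 iterations; one seed
governs the whole run and is recorded in the result and in the
command-line manifest.

**Acceptability.** At each threshold the winner of each iteration is the
strategy with maximal NMB; exact ties split the iteration's weight equally
(unbiased and deterministic). Fractions therefore sum to 1 at every
threshold. The published acceptability percentages are treated as
qualitative context only: the published PSA cost ranges are wider than a
gamma with the printed SD yields, so the original PSA parameterisation
evidently differed in undocumented ways, and matching its percentages
numerically is not a meaningful target.

## What the engine does not reproduce, and why

Running the engine with the published transition matrices, utilities and
discount rate does not reproduce the published per-strategy QALY totals
(e.g. control 1.70 over 20 years; the engine gets 4.69). The original
model was built in a GUI decision-tree tool and its internal structure —
whatever drives its much lower QALY accumulation — is not recoverable from
the publication. Two of its printed tables are even mutually inconsistent:
the lifetime QALY column for the subgroups (4.17/2.95/3.30) equals the
narrative's totals (5.68/4.46/4.82) minus the control's 1.51, i.e. it
prints increments as totals. The package therefore (a) certifies the engine
against independent closed forms and brute-force oracles rather than
against the published QALY column, (b) carries the published totals as
*inputs* (`trastuzumab_inputs()$reported_qalys`, using the narrative's
lifetime totals) so that ICER arithmetic on them reproduces the published
ICERs to ~0.1 % (the residual is their 2-decimal QALY rounding), and (c)
reproduces the published *structural* findings with its own engine: the
ICER declines with horizon, and the tornado ranking is led by trastuzumab
cost and stable utility.

## The synthetic cohort generator

`simulate_cohort()` emulates the registry data the analysis was estimated
from: per patient, an annual multinomial state path from the true matrix
(starting stable, stopping at death or end of follow-up), and a total cost
equal to a main gamma component plus, with a Bernoulli indicator, a second
component (the second chemotherapy line for 7/30 control patients; the
trastuzumab course for every patient of a trastuzumab arm). Defaults mirror
the study: arm sizes 30/38/14/96, fixed 8-year follow-up, the published
component means/SDs. Deliberately *not* emulated: a censoring process (only
mean/median follow-up was published, so follow-up is fixed-length),
covariates (they feed only analyses outside this package's scope),
state-dependent costs, and any dependence of the second-component indicator
on the state path. Passing the round-trip tests (estimate ∘ tabulate ∘
simulate recovers the true matrix to < 0.02 per cell at ≥ 10,000
patient-years per row) therefore validates the estimation pipeline's
correctness, not the realism of any particular registry.

The published pooled-arm total cost (€45,420.45) exceeds the sum of its
published components (€2632.91 + €38,069.95); the same holds for two
subgroups. The missing component is undocumented, so the fixtures carry the
printed totals for the model and the printed components for the generator,
independently — only the control arm's total is exactly the aggregate of
its components.

## Numerical choices and test scale

Row-stochasticity and trace conservation are enforced to $10^{-9}$;
closed-form engine checks run at $10^{-12}$; frontier extended-dominance
comparisons use a $10^{-12}$ strict guard. Degenerate inputs are defined
rather than left to float: zero-count rows self-loop, zero-SD distributions
degenerate to their mean, identical strategies flag as equivalent,
immortal cohorts return the lifetime cap with a warning.

The validation suite sizes its simulations for tight statistical checks at
interactive runtimes: 1000 random chains for conservation properties, a
9000-patient × 8-year synthetic cohort (≈ 60,000 patient-years) for matrix
recovery, 1000 Monte Carlo iterations for PSA moment checks, 200–300
iterations where only structure (sums, monotonicity, ties) is asserted.

## Known limitations

- Cohort-level only: no microsimulation, tunnel states or patient history
  dependence; annual cycles only.
- No age-dependent background mortality; with matrices lacking any death
  transition the lifetime horizon is truncated at the cap.
- Interval-censored transitions are counted at face value, as in the source
  estimator.
- The PSA samples costs and utilities only; parameter correlation and
  transition-probability uncertainty are not propagated.
- Expected value of perfect information is not computed.
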