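---
title: "Model and methods: daily-cycle Markov cost-effectiveness of inpatient nutritional support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutricea)
```

## The model

`nutricea` evaluates individualized nutritional support for hospitalized
chronic heart failure patients with a five-state Markov cohort model run in
daily cycles over 180 days. The states are the normal ward (every patient's
day-0 state: the modelled population is, by construction, hospitalized and
at nutritional risk on admission), an in-hospital complication state
(kept separate because complication days carry both their own tariff and a
higher death risk), intensive care, post-discharge survival, and death,
which is absorbing. Occupancy propagates by
$\pi_{t+1} = \pi_t P$ with one arm-specific, time-homogeneous transition
matrix $P$ per arm.

Three modelling assumptions shape everything downstream:

* **Whole-day accounting.** Occupancy is read at the start of each day and
  the occupied state accrues one full day of time and cost; no half-cycle
  correction is applied. All published quantities the package reproduces
  are consistent with plain `days × daily rate` arithmetic, and a
  half-cycle correction would break those identities.
* **Time homogeneity.** One matrix per arm for the whole horizon. This is
  what makes 365-day extrapolation well-defined, and it is also the main
  limitation (below).
* **No discounting.** Costs and effects are summed undiscounted over the
  horizon.

### Transition structure

The published state diagram names the transitions but does not enumerate
every arrow, so the structural mask is an explicit, configurable input
(`default_mask()`), with the following default reading: the ward exchanges
with every state; complication patients can recover to the ward, worsen to
the ICU, be discharged, or die; ICU patients return to the ward or the
complication state but are not discharged directly from intensive care;
discharged patients stay out, are readmitted non-electively (modelled as
`DISCHARGED → WARD`), or die. Whether a direct `ICU → DISCHARGED` arrow
exists cannot be settled from the source material; excluding it is this
package's choice, and any alternative reading is expressible by passing a
different mask to `validate_matrix()`, `calibrate_arm()` and
`estimate_matrix()`.

## Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| horizon | 180 | days | six-month modelling window; 365 for extrapolation |
| ward cost | 1650 | SF/day | published hospital statistics tariff |
| ICU cost | 4654 | SF/day | intensive-care complex-treatment DRG |
| complication cost | 1513 | SF/day | severe arrhythmia / cardiac-arrest DRG mix |
| nutrition, in/outpatient | 5 | SF/day | one oral supplement per day, pharmacy price |
| outpatient continuation | 0.2 | fraction | observed post-discharge continuation; 0.5/1.0 as scenarios |
| utility weight, alive states | 0.002 | /day | back-solved: 0.25 QALD / 123.84 ward days |
| WTP threshold | 100,000 | SF/life-year | conventional (hypothetical) Swiss threshold |
| Gamma SDs | 1/1/1485/3900/1477 | SF | published probabilistic-analysis SDs |

Inpatient nutrition is charged on **every in-hospital day** (ward +
complication + ICU): with the published life days this is
$135.81 \times 5 = 679$ SF per stay, exactly the published per-patient
nutrition cost, which reconciles the per-day price with the per-stay total.
Death accrues nothing. Utilities use a single back-solved daily weight for
all alive states; they are reported for completeness but never enter an
ICER (all ICERs are per unweighted life day or life year). Whether the
published utility column is on a 0–1 daily scale or rescaled from
quality-of-life instruments is not documented; the back-solved weight
reproduces the column only up to its own rounding, and one printed cell
(control ward, 0.23 vs 0.22) cannot be matched by any single weight.

## Calibration

The arm transition matrices behind the published tables were never
released, so `calibrate_arm()` reconstructs matrices that reproduce the
published *marginals*: per-state life days and 180-day mortality (85/321 =
26.5% intervention, 102/324 = 31.5% control). The objective is a weighted
squared relative error; mortality gets weight 5 (the trial's primary
endpoint), life days weight 1. Zero-valued targets switch to an absolute
scale (1 day; 0.01 dead fraction) so they still pull toward zero without a
division by zero.

Free parameters are the masked row probabilities of the four alive states
(17 under the default mask), mapped through a per-row softmax so every
iterate is exactly row-stochastic and mask-respecting. Ten random starts
(flat-Dirichlet rows) feed BFGS local searches; the three best are polished
at tighter tolerance and the winner returned. Numerical gradient steps are
set to 1e-5 (search) and 1e-7 (polish) — the default step of `optim` is far
too coarse for an objective whose minimum is ~1e-25 — and the inner cohort
summaries use matrix-power doubling
($S_n = I + P + \dots + P^{n-1}$ by halving) rather than a 180-step loop.
Everything is driven by one integer seed; identical seeds and targets give
bitwise-identical fits.

Two properties matter for interpretation:

* **Feasible targets fit essentially exactly.** With 17 free parameters
  and 5 targets the forward map is onto a neighbourhood of its image, and
  self-consistency tests (targets generated by the forward model) recover
  them to ~1e-12 relative error. Fits whose best achievable relative error
  exceeds 10% on any target are flagged infeasible — that threshold
  separates "the structure cannot express these targets" from noisy-but-
  usable fits.
* **The matrix is not identified.** Many matrices share the same marginals.
  Tests and reports therefore assert target recovery and downstream
  tallies, never matrix entries; quantities that depend on the matrix
  *beyond* its 180-day marginals — notably everything extrapolated to 365
  days — inherit this ambiguity and are treated as qualitative (see
  Limitations).

## The synthetic trial generator

`generate_trial()` emulates the patient-level data the analysis assumes:
each patient starts in the ward and steps daily by their arm's matrix, with
arm sizes 321/324 by default, emitted as a long patient-day table with a
single terminal death row. Each arm runs on its own RNG substream derived
from the master seed, so one arm's trajectories are invariant to changes in
the other arm's matrix. `estimate_matrix()` inverts the generator by
maximum likelihood (row-normalized transition counts, masked cells forced
to zero, never-visited states flagged), and `summarize_trial()` computes
the microsimulation analogues of the cohort tallies, with the dead fraction
read at the start of the final modelled day exactly as in the cohort model.

What the generator deliberately does **not** emulate: patient covariates
(age, ejection-fraction class, nutritional-risk score), duration-dependent
(semi-Markov) transitions, informative censoring, or patient-level cost
noise. Passing recovery tests therefore show that the estimation and
calibration machinery is correct *under the model's own assumptions*; they
cannot show that a time-homogeneous five-state chain is an adequate
description of real CHF trajectories.

## Sensitivity and threshold analyses

The deterministic analysis re-runs accrual over the cross of the supplement
price grid (5/100/1000 SF/day, applied to both in- and outpatient
nutrition) and the continuation-fraction grid (0.2/0.5/1.0), holding life
days fixed — treatment effects are not assumed to depend on the price of
the supplement.

The probabilistic analysis draws the five unit costs independently from
Gamma distributions moment-matched to their published means and SDs
(`shape = (mean/sd)^2`, `scale = sd^2/mean`), applies the same draw to both
arms (unit costs are common parameters), and recomputes the incremental
cost and ICER per draw with tallies held fixed — the published
probabilistic specification covers costs only, and a hook for transition
uncertainty (Beta/Dirichlet rows) is left out by default. Intervals are
2.5/97.5 percentiles, not normal approximations, because Gamma draws with
SD comparable to the mean are strongly right-skewed. Because accrual is
linear in unit costs and Gamma sampling is mean-preserving, the PSA mean
converges to the deterministic base case; the test suite checks exactly
that.

The threshold analysis asks the published question "how expensive could
nutritional support be and still be cost-effective at 100,000 SF per life
year?". `threshold_nutrition_cost()` solves $\mathrm{ICER}(c) = \lambda$
for the inpatient nutrition spend $c$ by bisection on a strictly increasing
ratio, to within 1 SF/life-year. The numerator always contains the
committed outpatient nutrition cost at the scenario's continuation
fraction — which is why the admissible maximum falls as the fraction rises,
matching the published ordering — and, in `full-incremental` mode, all
other incremental costs as well. Nutrition-only mode is the default: the
published maxima are irreconcilable with full-incremental arithmetic on the
published values, so the mode is exposed as a configuration flag rather
than hard-coded.

## Numerical choices and degenerate inputs

* Row-stochasticity is enforced to 1e-12 at validation; traces conserve
  mass to 1e-10 over any horizon tested.
* `icer()` never divides by zero: a zero effect delta yields a flagged
  undefined result, and the cost-effectiveness quadrant (dominant /
  dominated / trade-off) is always classified from the signs.
* Rounding happens only at render time (costs to whole SF, days and
  utilities to 2 decimals), so reports regenerate byte-identically from the
  stored JSON bundle.
* Degenerate chains (absorbing ward, immediate death) are first-class test
  cases, and the microsimulation's day-counting convention is pinned to the
  cohort model's so the two are comparable patient-for-patient.

Test problem sizes are chosen to keep Monte-Carlo standard errors small
relative to the tolerances being asserted: 100,000 patients for
cohort/microsimulation equivalence and for the calibrated-mortality check,
50,000 patients for transition-matrix round-trip recovery (3 binomial
standard errors entrywise), and 10,000 PSA draws for the linearity check.

## Limitations

* **Rounding floors.** Published cells were rounded before differencing:
  the published incremental table is internally inconsistent by 1 SF in
  the ICU row, and the ICU cost cells imply third-decimal life days
  (8733/4654 = 1.8765) that calibration to the two-decimal published
  targets cannot recover — a ~0.2% irreducible gap on those two cells.
* **Extrapolation ambiguity.** The 365-day results depend on transition
  structure beyond the 180-day marginals, which calibration cannot
  identify. The package reports them, and asserts only qualitative
  properties (alive days monotone in the horizon; annualized outpatient
  spend exceeding its 180-day value; threshold maxima ordered by
  continuation fraction).
* **Model scope.** No time-varying or duration-dependent transitions, no
  covariates, no indirect or societal costs, no QALY-based ICERs, and a
  fixed 0.95 EUR/SF display factor.
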