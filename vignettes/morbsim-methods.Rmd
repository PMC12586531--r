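---
title: "morbsim: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{morbsim: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morbsim)
```

`morbsim` is a dynamic discrete-time microsimulation of major illness —
a Cambridge Multimorbidity Score (CMS) above 1.5 — in an adult population
under counterfactual risk-factor scenarios. This vignette describes the
model, the assumptions baked into it, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the design choices
made where more than one reasonable implementation existed.

## The annual update loop

Each simulant is one row: sex, deprivation decile (1 = most deprived, fixed
for life — no social mobility), entry year, fixed lifetime exposure ranks, a
smoking history, and a state per modelled condition (free / active /
recovered). Years advance in this order:

1. **Ageing and entrants.** Everyone ages one year; new 30-year-olds enter.
2. **Exposure update.** Exposures are the stratum-year quantile at the fixed
   rank (scenario arms consult transformed trajectories).
3. **Incidence.** Bernoulli per at-risk simulant at
   `p0 × Π link RRs × Π parent RRs`, conditions in fixed registry order,
   parent effects reading the *previous* year's states.
4. **Recovery.** Cancers recover 10 years after onset (remission); five
   conditions recover stochastically and may recur; the rest are lifelong.
5. **Mortality.** Competing case-fatality hazards per active condition plus
   an other-cause hazard, combined as `1 − Π(1 − f·p_k)` with the stratum
   calibration factor `f`; one cause attributed proportionally to hazards.
6. **Outcome accumulation** into the results cube.

The ordering (incidence → recovery → mortality, parents lagged one year)
is a deliberate fixed convention: it removes any same-year feedback and
makes arm comparisons well defined. Because the packaged parent-condition
graph contains mutual dependencies (chronic pain and anxiety/depression each
raise the other's risk), a strict topological evaluation order cannot exist;
reading the prior year's states achieves the same goal for any order.

## Exposures

Seven exposure dimensions are modelled (BMI kg/m², SBP mmHg, total
cholesterol mmol/L, fruit and vegetables g/day, physical activity days/week,
cigarettes/day for smokers), plus derived environmental tobacco smoke (ETS).
A Gaussian copula gives each simulant one normal score per exposure with the
configured Spearman correlations; the score's percentile is the simulant's
rank in every year of life. The value is the quantile of a distribution
whose location moves log-linearly in age, deprivation and calendar time (log
link for positive exposures, logit on days/7 for physical activity, rounded
to whole days at consultation, as are cigarettes/day). Two assumptions
follow mechanically rather than being separately enforced: simulants stay in
the same exposure quintile group for life, and cross-exposure correlations
are constant over time.

Smoking is a three-state process (never / current / ex) with annual
initiation (closed above age 40) and cessation, pack-years accumulating at
cigarettes-per-day/20 while current, and years-since-quit counting while ex.
ETS exposure of non-smokers is proportional to stratum (sex × deprivation
quintile) smoking prevalence — probability `coupling × prevalence`,
truncated to [0, 1], default coupling 0.8 — realised through a persistent
per-simulant uniform so that any scenario lowering smoking prevalence can
only lower ETS exposure. The proportional form is this package's stand-in:
only the direction of the dependence is established, not its shape. ETS
prevalence is computed over the present cohort, ignoring differential
mortality, because trajectories are precomputed; at the mortality levels
simulated the induced error is second-order.

**Lags.** Every risk link consults the exposure value from `lag` years
earlier: fixed 5 years for non-cancer outcomes, 9 for cancers (means were
established, distributions were not, so fixed central lags are used).
Trajectories are precomputed back to `start_year − max(lag)` so the buffer is
full from the first simulated year; for entrants the pre-entry history is
the rank-implied value with age clamped at 30.

## Disease incidence and the PAF calibration

Continuous links follow a log-linear dose response on the excess over the
theoretical minimum risk exposure level (TMREL): `RR^max(x − TMREL, 0)` for
harmful factors, `RR^max(TMREL − x, 0)` for protective ones (fruit,
vegetables, activity), never below 1. ETS is a simple exposed/unexposed
lookup. Smoking links are status-based; the four cumulative links (COPD,
lung, breast, colorectal cancer) grow as `RR^(pack_years/20)` and, after
quitting, the excess decays exponentially with a 10-year half-life
(configurable) — cumulativeness is established, the decay form is this
package's choice. Non-cumulative smoking links are 100% reversible after
the link's lag.

Baseline incidence is never a free parameter: the base-case arm estimates
each calibration stratum's (sex × 10-year age band) mean multiplier `E[m]`
among the at-risk and every arm uses `p0 = target / E[m]` — the
population-attributable-fraction identity `p0 = target × (1 − PAF)` with
`PAF = 1 − 1/E[m]`. Freezing `E[m]` at base-case values is what lets a
scenario's lower multipliers translate into genuinely lower incidence. If a
stratum has no at-risk members when a scenario arm needs it, the pooled mean
multiplier is used with a one-time warning. Annual probabilities are clamped
at 0.999 to remain valid Bernoulli parameters. Incidence trends follow the
targets' log-linear continuation except chronic pain (frozen at the
reference year) and anxiety/depression and constipation (no trend), encoded
as per-condition trend rules in the rate table.

## Mortality

Case fatality per active condition is the stratum target multiplied by the
same risk links as incidence (equal relative risks on incidence and case
fatality is a core assumption; a switch disables the case-fatality side for
sensitivity analysis). Parent-condition RRs apply to incidence only. SBP,
smoking and physical activity — and prevalent CHD, stroke, type 2 diabetes
and COPD, a configurable list — additionally scale the other-cause hazard.
The combined probability is calibrated per stratum-year so expected deaths
match the all-cause envelope; because the competing-risk combination is
nonlinear in the scaling factor, the factor is solved by bisection (30
iterations, cap 10 with a warning when the target is unattainable, exact
zero when the target is zero). Factors are estimated on the base-case arm
and frozen for scenario arms. Recovered conditions carry no case fatality.

## Scenarios

Both families start in 2023 and are computed annually against that year's
base case. The TMREL family sets BMI, SBP, cholesterol, fruit and vegetables
to the iteration's sampled TMRELs, physical activity to 7 days, and turns
all current smokers into ex-smokers (initiation zero; pack-years frozen;
years-since-quit counting from the start year, applied uniformly so the
transform is idempotent). TMRELs with uncertainty (BMI 22, SBP 112,
cholesterol 4 mmol/L, fruit and vegetables 4 portions at 80 g/portion — the
standard UK survey convention for converting portions to grams) are drawn
once per Monte-Carlo iteration from a symmetric triangular distribution with
±10% support around the central value; only the existence of sampling
distributions is established, so a bounded symmetric form was chosen.
Physical activity's TMREL is exactly 7 days for everyone and smoking's is
zero, so neither is sampled.

The relative-improvement family removes `fraction` (default 0.10) of the
excess over the TMREL for the biological factors; mediation then lowers SBP
by 2.55 mmHg and cholesterol by 0.23 mmol/L per unit of BMI decrease for
base BMI ≥ 25, recomputed each year from that year's BMI delta (never
accumulated, so there is no double counting) and never crossing the
respective TMRELs; a switch disables mediation to give the direct-effect-only
sensitivity analysis. Smoking reduces the number of smokers by the fraction —
a persistent per-simulant uniform from a dedicated stream decides *who*
quits, so the same individuals quit in single-factor and combined arms — and
scales remaining smokers' consumption by `1 − fraction`. Physical activity
gives +1 day to a random fraction of those below 7 days, recipients
resampled annually against that year's base case (persistence of recipients
is not established; annual resampling matches the rule that improvements are
computed annually against the base case). Fruit and vegetables move together
(+10% in grams). ETS is always recomputed from the arm's smoking prevalence,
never set independently.

Common random numbers are implemented by keying every stream on
(master seed, iteration, purpose, year, condition) and indexing draws by
simulant id, so the baseline arm's outputs are unchanged by the scenario
list and a fraction-0 arm is bit-identical to the baseline.

## The synthetic-data generator

The generator emulates the *structure* of the real inputs: a deprivation-
and age-stratified initial cohort with jointly distributed exposures
(deprivation gradients point the directions seen in English data — higher
BMI and smoking, lower fruit/vegetables and activity in more deprived
deciles; SBP higher in less deprived deciles), log-linear secular trends
(BMI rising; SBP, cholesterol and smoking falling), seeded initial disease
prevalence with per-condition minimum ages, a Gompertz-like mortality
envelope improving ~1%/year, and annual age-30 entrants. Entrants are
generated up-front as fresh simulants; because the target counts are built
from the same envelope by the accounting identity
`counts(t+1) = counts(t) − expected deaths + entrants`, no annual rescaling
is needed and the identity holds exactly in simulation.

What it does **not** emulate: real English demography or survey weighting,
parameter uncertainty beyond the TMRELs, measurement error, within-year
variation, migration heterogeneity, period shocks (e.g. the COVID-19 era),
age-varying relative risks, or behaviour change after diagnosis. Passing
tests therefore demonstrate that the engine's mechanics are correct and
internally consistent — calibration closes, scenarios move outcomes in the
right direction with the right arithmetic — not that its outputs forecast
any real population. The packaged relative-risk magnitudes are illustrative
(roughly 1.1–3.0 per category), as are the condition rate surfaces; both
live in `inst/extdata/` as tab-separated tables with shipped checksums, and
the synthetic tables are named as such.

## Numerical choices and degenerate inputs

* Exposure values are clamped to spec bounds; ranks are kept in
  (10⁻⁶, 1 − 10⁻⁶); copula correlations are converted from Spearman via
  `2 sin(πρ/6)` and the matrix is checked for positive semi-definiteness
  (an infeasible matrix is an error).
* Stream seeds are a 31-bit polynomial string hash of the key; drawing
  restores the caller's RNG state.
* Uncertainty intervals are 2.5th/97.5th percentiles with linear
  interpolation on sorted per-iteration values (R's default quantile
  estimator), after per-iteration differencing to preserve pairing.
* A zero at-risk denominator yields a flagged `NA` rate; an empty
  calibration stratum falls back to the pooled multiplier with a warning;
  a single iteration yields a central estimate without an interval.
* CMS scoring operates on the 20 CMS conditions: several active modelled
  members of one CMS condition (both diabetes types, multiple cancers)
  contribute the weight exactly once. Recovered conditions do not score.

## Problem sizes

The test suite exercises generation at up to 50,000 simulants for
distributional checks and calibration closure, full-horizon (2013–2043)
runs at 10,000 simulants for the exact base-case/null-arm equivalence
check, and 1,000–2,000 simulants for identity and direction-of-effect
checks; these sizes give the stochastic checks 3-standard-error headroom
while keeping the default suite fast. Production-style analyses would
typically use larger cohorts and the default 100 iterations.

## Known limitations

Beyond the generator's scope above: lags are fixed integers rather than
distributions; the cumulative-smoking decay form and the ETS coupling form
are package choices; parent-condition RR magnitudes are illustrative; cause
attribution assumes proportionality among component hazards; and the CMS
threshold definition makes prevalence insensitive to severity changes within
the major-ill population.
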