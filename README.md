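# morbsim

Dynamic discrete-time microsimulation of major illness under risk-factor
scenarios.

`morbsim` is for epidemiological modellers who want to ask: *if population
exposure to modifiable risk factors improved, how much major illness would be
prevented or postponed over the next two decades — and who would benefit?*
It simulates the annual life course of synthetic adults (ages 30–100) whose
correlated exposures — body mass index (BMI), systolic blood pressure (SBP),
total cholesterol, fruit and vegetable consumption, physical activity,
smoking history and environmental tobacco smoke (ETS) — drive the incidence
and case fatality of 26 modelled long-term conditions. Conditions aggregate
to the 20 conditions of the Cambridge Multimorbidity Score (CMS); **major
illness** is a CMS score above 1.5. Because no survey or health-record data
can be redistributed, the package ships a synthetic-population generator
that emulates the structure of those inputs, so every mechanism is fully
testable end to end.

## The model

Each simulant carries a fixed lifetime percentile rank per exposure. The
value in year *t* is the quantile of the stratum-year distribution at that
rank, with the location evolving log-linearly in calendar time — so
exposure quintile-group membership and rank correlations persist for life.
Disease risk follows a multiplicative relative-risk model with lags: the
annual incidence probability of condition *c* for simulant *i* is

```
p_ic(t) = p0_c(stratum, t) × Π_links RR^max(x_i(t − L) − TMREL, 0) × Π_parents RR
```

where `x_i(t − L)` is the exposure consulted at the link's lag `L` (5 years
for most conditions, 9 for cancers), TMREL is the theoretical minimum risk
exposure level (e.g. BMI 22 kg/m², SBP 112 mmHg), and parent terms are
prevalent conditions acting as risk factors (previous year's states, so
there is no same-year feedback). The baseline `p0` is backed out from
stratum target rates through the population-attributable fraction,
`p0 = target / E[Π RR]`, so the base case reproduces its targets by
construction. Risk-factor effects on case fatality equal those on incidence
(with a sensitivity switch to turn them off), smoking carries a cumulative
pack-year effect for COPD and lung/breast/colorectal cancer that decays
after quitting, SBP, smoking and physical activity additionally modify
non-modelled-cause mortality, and total mortality is calibrated to an
envelope on the base-case arm with the calibration frozen across scenario
arms.

Scenarios transform base-case exposures from 2023 onward:

* **Theoretical minimum risk** — every individual at the TMREL (smokers all
  become ex-smokers, initiation stops, ETS disappears with smoking).
* **10% relative improvement** — each year, 10% of the excess over the TMREL
  is removed (for BMI 28 vs TMREL 22 the counterfactual is 27.4); smokers are
  10% fewer and smoke 10% less; 10% of those below 7 active days gain one
  day; fruit and vegetables rise 10%. BMI improvement also lowers SBP
  (2.55 mmHg) and total cholesterol (0.23 mmol/L) per BMI unit for BMI ≥ 25.

All arms replay under common random numbers, so arm differences reflect the
intervention, not sampling noise. Outputs accumulate into a results cube
(iteration × scenario × year × stratum) from which prevalence, incidence,
mortality per 10,000, case-years prevented/postponed, age-standardised and
deprivation-quintile summaries are computed with Monte-Carlo uncertainty
(mean and 2.5th–97.5th percentiles across iterations).

The packaged relative risks are **illustrative magnitudes, not
meta-analytic estimates**: the engine's behaviour, not its parameter
provenance, is what this package delivers, and its outputs should not be
read as projections for any real population.

## Worked example

```r
library(morbsim)

reg <- load_registry()
reg
#> morbsim condition registry
#>   modelled conditions: 26 (20 CMS conditions)
#>   risk links:          45 (4 cumulative smoking links)
#>   parent-condition RRs: 24
#>   CMS weight range:     0.08 - 2.5

cms_score(c("hypertension", "asthma", "hearing_loss"))  # 0.36
is_major_illness(cms_score("dementia"))                 # TRUE: 2.50 > 1.5

cfg <- run_config(
  n_simulants = 5000L, n_iterations = 4L, master_seed = 1L,
  scenarios = list(scenario("tmrel_all", "tmrel"),
                   scenario("improve10_all", "relative_improvement"))
)
run <- run_simulation(cfg)

summarise_cube(run$cube, "prevalence", "baseline", 2043)
#> 0.269542 (95% UI 0.262214, 0.279698) over 4 iterations
summarise_cube(run$cube, "prevalence", "tmrel_all", 2043, comparator = "baseline")
#> 0.028667 (95% UI 0.0242687, 0.0317556) over 4 iterations
summarise_cube(run$cube, "prevalence", "improve10_all", 2043, comparator = "baseline")
#> 0.00740461 (95% UI 0.00566643, 0.00924443) over 4 iterations
```

Read: in this synthetic population, major-illness prevalence among adults
30+ reaches about 27% in 2043 under continuing trends; eliminating all
excess risk from 2023 lowers that by about 2.9 percentage points, and a 10%
improvement in all risk factors by about 0.7 points — the familiar pattern
that even large risk-factor gains shift mid-term prevalence modestly,
because ageing dominates and improved survival keeps people living (longer)
with illness. `case_years_prevented()`, `major_illness_incidence()`,
`standardise_to_reference()` and `inequality_gradient()` compute the
corresponding case-year, incidence, age-standardised and deprivation-
gradient summaries; `validate_run(run)` reports standardised discrepancies
between the base case and its calibration targets over the 2013–2022
burn-in.

## Package layout

* `R/registry.R` — condition registry, CMS scoring, validation.
* `R/population.R` — synthetic population generator and calibration targets.
* `R/exposures.R` — rank-based exposure projection, smoking dynamics, ETS.
* `R/scenarios.R` — TMREL and relative-improvement transforms, mediation.
* `R/disease.R` — relative risks, PAF calibration, incidence, recovery.
* `R/mortality.R` — case fatality, other-cause mortality, envelope calibration.
* `R/outcomes.R` — results cube metrics and uncertainty summaries.
* `R/runner.R` — iteration/scenario orchestration and the annual loop.
* `inst/extdata/` — parameter tables (tab-separated, with checksums).
* `vignettes/morbsim-methods.Rmd` — the methods vignette.
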