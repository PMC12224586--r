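---
title: "Modelling sodium-reduction policies with a proportional multi-state lifetable"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sodium-reduction policies with a proportional multi-state lifetable}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmsalt)
```

## The model

`pmsalt` estimates the health and healthcare-cost impact of population
sodium-reduction policies with a proportional multi-state lifetable
(PMSLT). The structure has three interconnected parts:

1. **Risk-factor module.** Each counterfactual scenario shifts the mean
   usual sodium intake of every adult DRI age/sex stratum (male/female ×
   19–30, 31–50, 51–70, 71+). The intake change maps linearly to a change
   in systolic blood pressure (SBP), and SBP maps to disease incidence
   through a log-linear relative risk, constant per 20 mmHg within age
   bands. The resulting potential impact fraction on incidence is, in the
   default mean-shift form,
   $\mathrm{PIF}(a,s,d) = 1 - \mathrm{RR}_{20,d}(a)^{\Delta \mathrm{SBP}(a,s)/20},
   \qquad \Delta \mathrm{SBP} = -\beta(a)\,\Delta\mathrm{Na}/1000,$
   with $\beta$ in mmHg per 1,000 mg/day sodium. A distributional PIF over
   a discretised intake distribution is available for sensitivity; under
   the log-linear risk a uniform shift of the distribution reduces exactly
   to the mean-shift form, which is why the mean-shift default is adequate
   when interventions act on stratum means.

2. **Disease models.** Ischemic heart disease (IHD) and stroke are each a
   three-state Markov model — disease-free, diseased, dead from that
   disease — run in annual cycles on cohort proportions with
   rate-to-probability conversion $q = 1 - e^{-\text{rate}}$ and no
   remission. The counterfactual multiplies incidence by $1-\mathrm{PIF}$;
   case fatality is common to both arms. Because other-cause mortality is
   handled by the lifetable (the "proportional" separation),
   $S + C + D$ is conserved within each disease model.

3. **Lifetable.** A closed cohort of the adult population (ages 19–100 at
   baseline) is followed until age 100. The counterfactual lifetable
   subtracts the change in per-disease mortality from all-cause mortality,
   $m'(a) = \max\{0,\; m(a) - \sum_d [mx_d^{\mathrm{base}}(a) -
   mx_d^{\mathrm{scen}}(a)]\}$, builds survivorship
   $l(a+1) = l(a)(1 - q(a))$ with trapezoid life-years
   $L(a) = (l(a)+l(a+1))/2$, and accumulates three outcomes per scenario:
   prevented incident cases (undiscounted counts), QALYs gained and
   healthcare-cost savings (both discounted).

QALYs weight life-years by a background utility per 10-year age band and
multiplicative prevalence-weighted disease decrements,
$w = w_{bg}(a)\prod_d (1 - \mathrm{prev}_d \cdot \mathrm{dec}_d)$; an
additive combination is available via `qaly_weight(..., combine =
"additive")`. Multiplicative combination was chosen as the default because
it can never produce negative weights and is the conservative standard when
the joint disutility of comorbidity is unknown. Costs accrue per prevalent
case-year — the diseases modelled exert costs chronically — with no
separate first-year event cost.

## Counterfactual scenarios

Ten scenarios ship with the package (`default_scenarios()`, also as YAML in
`inst/extdata/scenarios.yaml`), spanning three policy families:

* **Intake recommendations** — capping each stratum mean at the Adequate
  Intake (1,500 mg/day, S1) or the WHO recommendation (2,000 mg/day, S2).
  From a baseline mean of 2,758 mg/day these require reductions of 1,258
  and 758 mg/day (3.14 and 1.89 g/day of salt at 2.5 g salt per g sodium).
* **Packaged-food reformulation** — a 459 mg/day reduction (S3, roughly a
  17% cut reaching the ~2,300 mg/day national target).
* **Front-of-package labelling** — proportional purchase-shift effects of
  4.7%, 6.4% and 7.8% (S4–S6) and food-substitution deltas of 73, 131,
  182 and 259 mg/day for 30/50/70/100% of adult consumers (S7–S10).

Interventions are one-sided (a target never raises an intake; a delta never
drives it negative) and apply only to ages 19+, mapped to 1-year ages by
DRI band membership. The scenario effect is assumed to persist for the
lifetime of the cohort; this persistence assumption is configuration in the
sense that a decaying effect can be emulated by scaling the scenario
parameter, but no decay machinery is built in.

## Key parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| discount rate | 0.015 | per year | sensitivity 0 and 0.03 |
| horizon | lifetime | years | sensitivity 10 and 50 |
| salt factor | 2.5 | g salt / g sodium | the factor consistent with the scenario table, not the stoichiometric 2.542 |
| SBP slope $\beta$ | 1.0 / 1.5 / 2.0 | mmHg per 1,000 mg/day | ages <40 / 40–59 / 60+; illustrative, non-authoritative |
| RR per 20 mmHg, IHD | 1.90 … 1.20 | — | declining over bands <50 … 80+; illustrative |
| RR per 20 mmHg, stroke | 2.50 … 1.25 | — | declining over bands <50 … 80+; illustrative |
| utility decrements | IHD 0.07, stroke 0.12 | — | multiplicative combination |
| Monte Carlo iterations | 5,000 | — | scaled down in tests and examples |

The SBP slopes and relative risks are deliberately exposed as configuration
(`default_effect_model()`): their authoritative values live in
meta-analyses, not in this package, and every analysis should substitute
its own. Discounted streams accrued during simulation year $k$ (0-based)
are valued at the year-end factor $(1+r)^{-(k+1)}$; this convention shifts
all present values by a constant factor and no ordering or difference-based
conclusion depends on it.

## Synthetic inputs: what they emulate, and what they do not

`synthetic_inputs()` generates every table the pipeline needs, with the
structure of the corresponding national sources:

* **Population and mortality** — a 1-year population pyramid whose counts
  are multinomial around the survivorship of a Gompertz–Makeham hazard
  $m(a) = \min(1, \alpha + \beta e^{\gamma a})$ (defaults
  $\alpha = 5\times10^{-4}$, $\beta = 3\times10^{-5}$, $\gamma = 0.095$,
  giving adult life expectancy in the high-70s). Real populations carry
  cohort effects (baby booms, migration) that the smooth pyramid does not.
* **Disease epidemiology** — incidence zero below 20, flat to 35, then
  log-linear in age (IHD reaching ~1% per year at 90); case fatality
  constant below 35 and log-linear above; male excess factors 1.4 (IHD)
  and 1.2 (stroke). Prevalence and cause-specific mortality are **not**
  sampled independently: they are produced by forward-running the
  three-state process with the known case fatality, so the back-calculation
  has a ground truth and can be validated by parameter recovery.
  Optionally the grids are re-aggregated to 5-year source groups (20 to
  90+) to exercise the preparation pipeline.
* **Sodium intakes** — stratum means shaped like survey data (male >
  female, declining with age) rescaled so the population-weighted mean is
  exactly the configured 2,758 mg/day baseline; standard errors are free
  configuration, as usual-intake estimation is out of scope.
* **SBP** — survey bands (6–11 … 60–79) with the 80+ band carried forward
  from 60–79 per sex, and the youngest band carried down to age 0.
* **Costs and utilities** — attributable direct costs per EBIC-style band
  (0–14, 15–34, 35–54, 55–64, 65–74, 75+), sex and disease, built as a
  per-case target times the band's prevalent cases with small lognormal
  noise; unattributable totals as a 25% share, allocated back
  proportionally to attributable shares; a healthcare-CPI factor of 1.17
  inflates to 2019 CAD; background EQ-5D-like utilities by 10-year band.

Passing tests on these inputs demonstrate the correctness of the machinery
— conservation, orderings, parameter recovery, oracle agreement — not the
magnitude of any real-country estimate. National results require the real
input extracts, which are deliberately out of scope.

## Age-grid preparation

Source tables arrive at coarser granularity than the 1-year lifetable grid:

* **Counts** are disaggregated by monotone cubic (Hyman) interpolation of
  the cumulative sum, differenced at integer ages. This was chosen over
  regression-based temporal disaggregation because it guarantees
  non-negative values and exact group totals by construction. Rates are
  disaggregated via counts (rate × group population), matching the
  "smooth counts, conserved totals" behaviour.
* **Old-age extrapolation** fits a polynomial (default order 2, exposed as
  1–3) to the oldest six group midpoints and evaluates it at ages 91–100,
  clamped to $[0, 1]$. Open-ended terminal groups (width ≥ 10 years) use
  midpoint $\mathrm{lo} + 2.5$; this convention is arbitrary but fixed, and
  polynomial inputs of degree ≤ the fitted order are recovered exactly.
* **Bands** (SBP, costs, utilities) expand piecewise-constant with
  inclusive lower edges; age intervals are closed $[lo, hi]$.

## Case-fatality back-calculation

The direct estimator is the definitional ratio
$f(a) = \text{cause deaths}(a) / \text{prevalent cases}(a)$, with ages
under a 5-prevalent-case floor filled from the nearest valid age and ages
below 35 replaced by their prevalence-weighted mean (the ratio is unstable
where cases are sparse). Because the generator's deaths arise from the
annual probability $1 - e^{-f}$, the plain ratio estimates that
probability, which understates the rate as $f$ grows; the refinement step
closes this gap. `refine_case_fatality()` forward-runs the three-state
recursion from age 0 with the observed incidence and, age by age, solves in
closed form for the case fatality that reproduces the next observed
prevalence (clamped to non-negative rates, capped at 5/year), re-imposing
the below-35 constancy between sweeps. On consistent inputs this converges
in one or two sweeps and is an exact fixed point; on inconsistent inputs it
stops on a residual-change tolerance (default 1e-10, 25 sweeps) and flags
non-convergence with a warning rather than an error, returning the per-age
relative prevalence residuals as diagnostics. No smoothing is applied above
age 35. Recovery on forward-simulated epidemiology is better than 5% mean
absolute relative error over ages 40–90 (in practice ~1e-13).

## Monte Carlo uncertainty

`monte_carlo()` draws, per iteration: log-normal multipliers for the RRs
per 20 mmHg (log-sd 0.08) and case fatality (log-sd 0.1), normal draws for
the SBP slopes (CV 0.15) and the stratum intake means (their standard
errors), and a gamma multiplier for per-case costs (CV 0.2) — the
quantities whose uncertainty is parameter-like rather than structural.
Uncertainty intervals are empirical 2.5th/97.5th percentiles; the point
estimate is the unperturbed deterministic run (both are reported, as the
central tendency of a skewed Monte Carlo cloud need not match the
deterministic run). Iterations use independent substreams drawn from the
master seed, so results are reproducible and independent of execution
order. Degenerate (zero-variance) settings collapse the intervals onto the
deterministic run exactly, which is tested.

## Numerical choices and degenerate inputs

* Rate→probability conversion is $q = 1-e^{-r}$ throughout, keeping
  probabilities in $[0,1]$ for any non-negative rate.
* Mortality adjustment clamps at 0; PIFs are capped at 1; a total
  intervention (PIF = 1) zeroes incidence without side effects.
* Cohorts aged 100 at baseline contribute no person-years (the simulation
  stops at age 100); the terminal year's events are included for all
  younger cohorts.
* Zero-prevalence strata with zero cost divide to zero cost per case;
  zero-prevalence with positive cost is an error, as is an all-zero
  attributable split facing a positive unattributable total.
* The null scenario is an exact fixed point: both arms execute the same
  code path, so every difference output is identically zero at machine
  precision.

## Problem sizes

The shipped defaults simulate a population of $10^6$ (configurable), 164
cohorts (82 start ages × 2 sexes), 2 diseases and 10 scenarios; a
deterministic scenario run takes tens of milliseconds, so the full
10-scenario sweep, the discount/horizon sensitivity grid and a few hundred
Monte Carlo iterations all run interactively. The 5,000-iteration default
for production uncertainty intervals takes a few minutes.

## Known limitations

* Two diseases only; no comorbidity interaction beyond shared lifetable
  mortality, no remission state.
* Incidence and case fatality are frozen at their baseline-year values; no
  secular trends.
* The intake→SBP→disease chain ignores non-SBP pathways of sodium and all
  non-sodium nutrients.
* Averted deaths' unrelated future healthcare costs are not re-added; net
  savings are therefore the gross disease-cost difference (a recognised
  open debate in multi-state lifetable costing).
* Synthetic inputs are structurally faithful but numerically illustrative;
  headline counts scale with the synthetic population and parameters.

## A minimal run

```{r example, eval = FALSE}
raw <- synthetic_inputs(seed = 1)
model <- prepare_inputs(raw)
res <- run_scenario(model, default_scenarios()$S3)
subset(res, sex == "both")

ui <- monte_carlo(model, default_scenarios()$S3,
                  mc = mc_settings(n = 200, seed = 1))
sens <- sensitivity_suite(model, default_scenarios()$S3)
```
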