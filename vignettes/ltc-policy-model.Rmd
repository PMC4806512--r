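---
title: "Modelling long-term care demand and caregiver labor-market withdrawal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling long-term care demand and caregiver labor-market withdrawal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ltcsim)
```

## The model

`ltcsim` is a deterministic stock-and-flow model of long-term care (LTC) in
an aging population, written as annual difference equations. It answers a
policy question: as the number of elderly with
activities-of-daily-living (ADL) disability grows, how many primary informal
family caregivers will withdraw from the labor market, and does expanding
formal LTC services return more caregivers to work than the paid workers
those services themselves require?

The model has three coupled layers.

**Population.** A cohort-component projection in one-year age groups by sex.
Each year every cohort loses deaths (life-table-style mortality
probabilities), gains net migration, and survivors move up one age; births
enter age 0 as an aggregate fertility rate applied to women aged 15–44; the
top group (100+) is an open-ended accumulator. Mortality and fertility are
held constant over the simulation. An annual step is the default; a
sub-annual Euler option exists (`time_step < 1` in `step_population()`) but
all published-style output uses annual steps. Cohorts driven negative by an
extreme net outflow are clipped at zero with a warning — a deterministic
guard that matters only for pathological sensitivity draws.

**Disability.** Elderly (60+) with at least one ADL limitation needing human
assistance are tracked in three severity groups: low (1–2 limitations),
medium (3–4), high (5+). Stocks are initialized from an age-band prevalence
table (community survey values, with nursing-home residents added back to
the high group, since community surveys miss them). Two projection modes are
provided because the source evidence supports either reading:

* `stock_flow` (default): an explicit inflow — annual incidence 0.00768
  applied to the non-disabled 60+ population, split 0.36/0.24/0.40 across
  severity at onset — and an outflow, the disabled-elderly mortality 0.1134
  per year. No transitions between severity groups and no recovery are
  modelled.
* `prevalence`: the age-band prevalence is simply re-applied to each year's
  pyramid. The two modes agree exactly at initialization.

**Care arrangements and labor.** Disabled elderly occupy one of five
arrangements: nursing home; home with home- and community-based services
(HCBS); home with a foreign domestic worker (FDW); home with both; home with
no paid services. Nursing-home beds are a capacity: occupancy moves toward
the bed-limited target with a first-order delay (adjustment time 1.5 years),
and beds go to the highest-severity elderly first. The home-dwelling
population is re-partitioned each year from the current HCBS-uptake and
FDW-proportion levers, applied as independent fractions — the simplest
partition consistent with the two marginal proportions, and memoryless
because no transition rates between home arrangements are available.

Weekly primary-caregiver hours come from surveyed tables: 31/36/42 hours by
severity without paid services, 25/48/37 with HCBS. When an FDW is present
she provides 70% of the care hours, leaving the primary caregiver 30% of the
tabulated load; nursing homes provide all hours. Note the surveyed anomaly:
medium-severity caregivers *with* services report more hours (48) than
without (36). We keep the tabulated values — they are the measured
quantities, carry the published sensitivity ranges, and rounding them away
would be silent data editing — but the anomaly has visible consequences
discussed below.

Hours convert to labor-market withdrawal through a piecewise-linear
*dropout curve* anchored at the instrumental-variable regression results:
11, 22 and 55 percentage-point reductions in participation at 10, 20 and 40
hours/week, through the origin, for caregivers in households **without** an
FDW (no association was found for FDW households, so their reduction is
identically zero). Beyond the last anchor the curve continues at its mean
slope over the anchor span (1.375 pp/hour) and is clamped at 100. Expected
dropouts in a care-mix cell are
`count x employable_fraction (0.65) x reduction(hours)`; one caregiver per
care recipient (a dyad) is assumed.

Paid-LTC staffing uses patient-to-staff ratios 5 (nursing homes), 7 (HCBS)
and 1 (live-in FDW). A household using both HCBS and an FDW is counted
once, under the FDW: the live-in worker already provides 70% of the hours,
and charging the household twice would book two paid workers for one care
recipient. This choice was genuinely open (the sources do not state it); we
verified that double-counting inflates the HCBS staffing bill enough to
push the pro-HCBS policy's labor-requirement ratio above the pro-FDW
policy's, inverting the published qualitative ordering, while
single-counting reproduces it. `paid_labor_required()` keeps a
`double_count_fdw_hcbs` switch for the other reading.

## Scenarios

Six policies are specified as piecewise-linear lever ramps (the sources give
endpoints, plus one mid-knot for beds):

| scenario | beds | HCBS uptake | FDW proportion |
|---|---|---|---|
| `no_ltc` | 0 | 0 | 0 |
| `current` | 9,750 (2012) → 14,900 (2020) → 22,400 (2030) | 0.20 → 0.30 | 0.49 → 0.60 |
| `pro_hcbs` | as current | 0.20 → 0.80 | as current |
| `pro_fdw` | as current | as current | 0.49 → 0.80 |
| `pro_nh` | all high-severity placed from 2013 | as current | as current |
| `all_in` | as pro_nh | 0.20 → 0.80 | 0.49 → 0.80 |

Lever ramps run 2013–2030 inside a 2010–2030 simulation window. The
pro-nursing-home rule bypasses the capacity-adjustment delay (capacity is
expanded to meet high-severity demand and held there). The opening bed count
is the tabulated 9,750 at 2012; a `bed_start_override` config key installs
the alternative 9,300-at-2013 reading. The `no_ltc` counterfactual is always
run on the same inputs and defines the comparison columns: *increase in
caregivers working* is the scenario's caregivers-in-market minus the
counterfactual's; *new paid labor* is the scenario's staffing (the
counterfactual needs none); their quotient is the *labor-requirement ratio*.
For the counterfactual itself these columns are reported missing, matching
the published table's dashes.

```{r scenarios}
runs <- run_scenarios()
summarize_outcomes(runs)[seq_len(10), ]
```

Counts are rounded to the nearest hundred and ratios/percentages to one
decimal, the published rounding.

## The two-stage IV probit

Caregiving hours are endogenous to employment (those out of the labor market
have more time to give care), so the hours→participation relationship is
estimated with a two-stage procedure: stage 1 regresses weekly caregiving
hours on the care recipient's severity-category indicators (the
instruments) and caregiver covariates by least squares; stage 2 fits a
probit of labor-force participation on the stage-1 fitted hours and the same
covariates. Severity of the *care recipient* shifts hours strongly but has
no direct channel to the *caregiver's* employability, which is the exclusion
restriction. Survey preparation caps hours at 112/week (16/day), drops
never-employed caregivers and those caring for more than one person.
Standard errors, when wanted, come from a nonparametric bootstrap over
records (default 500 resamples, `iv_probit_boot()`), which propagates the
generated-regressor uncertainty of stage 1. A fitted model exports a dropout
curve via predicted-probability differences on an hours grid
(`as_dropout_curve()`), covariates held at sample means.

The default scenario engine does **not** re-estimate this regression: it
uses the published anchor results directly, because the originating
microdata are not distributable. The estimation module exists so the curve
can be re-derived from user-supplied or synthetic survey data.

## Synthetic data

Everything the pipeline consumes can be generated in code.

**Demography.** `make_demography()` builds a stable-population age
structure: counts at age $a$ proportional to $l(a)e^{-ra}$ with
survivorship $l$ from a Gompertz–Makeham schedule
($m(a) = c + a_g e^{ba}$, defaults $a_g = 3\times10^{-5}$, $b = 0.095$,
$c = 3\times10^{-4}$), multiplied by a Gaussian cohort bulge (scale 8,
center age 55, sd 10) representing a baby-boom generation about to cross
age 60. The defaults — total population 3.9 million, $r = 0.015$,
fertility 0.043 births per woman-year (a total fertility rate near 1.3
spread over ages 15–44), net migration +19,500/year — were chosen once so
that the implied dyad trajectory matches the published projection scale
(45,600 dyads in 2013 rising to 100,300 by 2030; the fixture gives
45,900 → 102,500). That scale matters qualitatively: the fixed bed ramp
must remain scarce relative to high-severity demand, as it is in the study
setting, for the policy comparisons to be meaningful. What the generator
does *not* emulate: real census margins, cohort-specific
fertility/mortality history, sex-differential mortality, or migration age
profiles beyond a working-age placement. Passing tests on this fixture
therefore demonstrate internal consistency and qualitative behavior, not
forecasts for any real population.

**Caregiver survey.** `make_caregiver_survey()` is the forward model of the
two-stage system with known coefficients. Stage-1 defaults put mean hours
at the surveyed severity means (31/36/42) with residual sd 15 h; stage-2
defaults ($\gamma_0 = 0.9$, $\gamma_1 = -0.035$) reproduce participation
reductions close to the published 11/22/55 pp anchors. Participation is
generated from the *structural* (systematic) hours, so the exclusion
restriction holds by construction and the two-step estimator's estimand is
the generating coefficient; FDW households get a zero hours effect. An
`endogeneity_rho` option correlates the two noise terms (0.5 in the
endogenous preset) to demonstrate why instrumenting is needed: the naive
probit on observed hours is then biased while the two-step estimate is not.
Covariates are independent coin flips — a documented simplification, which
is why the recovery tests speak to estimator correctness rather than to any
real covariance structure.

## Monte-Carlo sensitivity

The designated uncertain parameters are the FDW proportion and the two
surveyed hours blocks (each severity cell independently). Each run draws
every parameter from Uniform(base × 0.8, base × 1.2); the FDW draw is
applied as a multiplier so ramped FDW levers scale coherently. The model is
re-run per draw (1000 runs at protocol scale) and each scenario × metric ×
year is summarized by its mean and central 95% interval, read as the
2.5th/97.5th percentiles across runs — the source phrasing ("minimum and
maximum values at 95 percent confidence level") is ambiguous between
per-run and across-run readings; across-run percentiles are the standard
interpretation and are what we report. Draws are keyed by
(seed, run index) through a fixed integer hash, so results are independent
of execution order and bit-reproducible. A one-at-a-time mode
(`run_sensitivity_oat()`) evaluates band edges for tornado-style output.

## Numerical choices and degenerate inputs

* Ramps clamp outside their knot range (no extrapolation of policy levers).
* The dropout curve clamps to [0, 100] pp; its beyond-anchor slope is the
  mean anchor slope, which keeps the extension insensitive to the spacing
  of the last two anchors.
* The first-order capacity update caps the per-step fraction at 1, so
  adjustment times below one year converge without overshoot; if beds fall
  below occupancy the stock is rescaled to capacity.
* Severity shares must sum to 1 within 1e-9; care-mix partitions are exact
  by construction and asserted to 1e-6 relative in tests.
* Probit non-convergence and complete separation (e.g. all participants
  employed) raise errors rather than returning silent fits.
* The disabled stock is validated against the 60+ population each step.

## Problem sizes in the test suite

The suite exercises the full pipeline at sizes chosen to keep a complete
run comfortable on a laptop: parameter-recovery uses 100 synthetic surveys
of n = 20,000; the null-calibration experiment 200 surveys of n = 2,000;
sensitivity properties a 200-run reduced protocol (the full protocol is
1000 runs); scenario properties run the full 2010–2030 window for all six
policies. These are the package's own verification sizes, not limits of the
method.

## Known limitations

* Absolute projections are driven by the synthetic demography and are not
  forecasts; only arithmetic identities, configuration values, the anchor
  curve, and qualitative orderings are reproduced from the source study.
* The medium-severity services-hours anomaly (48 > 36) makes additional
  HCBS uptake nearly neutral for medium-severity caregivers; in a narrow
  early-ramp window the pro-HCBS option can exceed the current policy's
  dropout percentage by ~0.002 pp. Orderings are asserted at the published
  comparison years (2020, 2030), where they hold.
* No waiting-list queue beyond the first-order delay, no means testing, no
  prices or wages, no caregiving-hours threshold effects, no recovery from
  disability, and no movement costs between care arrangements.
* One caregiver per care recipient; caregiver supply constraints (e.g.
  shrinking family size) are outside the model.
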