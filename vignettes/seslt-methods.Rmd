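---
title: "Methods: SES-stratified life tables and relative survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SES-stratified life tables and relative survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seslt)
```

## The mortality model

For one sex-race stratum in one geographic area, let `D(i, age, year)`
and `P(i, age, year)` be deaths and population in county `i` at single
ages 30-84. The package models

```
D ~ Poisson(P * lambda),
log(lambda) = f(age) + g(year) + sum_j beta_j SESQ_j(i) + sum_j gamma_j SESQ_j(i) * age
```

where `f` and `g` are restricted cubic splines and `SESQ_j(i)` indicates
county `i`'s SES quintile. This is a log-link Poisson GLM with a
log-population offset, fitted by IRLS (`fit_poisson_lt()`). Key
assumptions: deaths are conditionally independent Poisson counts given
exposure (no overdispersion term), the age and year effects are additive
on the log scale, and SES modifies the age *slope* linearly (the
interaction uses untransformed age, not the spline).

Tunable parameters, with defaults and rationale:

* **Age knots** (years): 32, 40, 55, 70, 77, 82. Six knots concentrate
  flexibility where adult log-mortality curvature lives (late-midlife
  acceleration), while staying identifiable in a 55-age window.
* **Year knots** (calendar years): 1992, 1997, 2002, 2007, 2012 — one
  per quinquennium across the intended 1992-2012 span. For shorter
  simulated spans any >= 3 strictly increasing knots may be supplied, or
  `NULL` to drop the term.
* **Grouping window** (years, odd): 3. `aggregate_rates()` sums deaths
  and exposure over `[center-1, center+1]` and labels the sum with the
  center year, stabilizing small-county rates. Windows at the edge of
  the observed span truncate to the available years rather than pad.
* **SES form**: `quintile5`, `level2` (low = Q1-Q3 vs high = Q4-Q5,
  which balances deaths while preserving the main SES contrast), or
  `none`.
* **Reference SES level**: Q5 for quintiles, `low` for two levels
  (configurable). The model is invariant to this choice; fixing the
  highest-SES quintile as reference makes the `beta_j` read directly as
  log-rate excesses of lower-SES counties.
* **Fitting ages**: 30-84 only. Younger ages have too few deaths for
  county-level stability and populations at 85+ are not available by
  single age; both tails are instead reconstructed from a reference
  table (below).

`select_model_spec()` encodes the sparsity ladder: candidates ordered
state+quintile5, state+level2, state+none, region+quintile5,
national+level2, national+none, and the first whose every area-by-SES
cell holds at least `min_cell_deaths` (default 25) with every area unit
totalling at least `min_total_deaths` (default 10,000) wins. The
thresholds are configurable because published model assignments report
outcomes, not the underlying cutoffs; the defaults are conventional
sparse-cell guards.

### Numerical choices

The spline basis (`rcs_basis()`) is Harrell's: `k` knots give one linear
plus `k-2` nonlinear columns, each nonlinear column normalized by the
squared knot range. IRLS stops when the relative deviance change falls
below 1e-8 or after 100 iterations; rank deficiency and non-convergence
are errors, not warnings, because a silently aliased SES column would
corrupt every downstream life table. With the canonical log link the
score equations force fitted deaths to match observed totals within each
SES level — the test suite checks this balance to 1e-6, and checks that
splitting a county into identical halves leaves the fit unchanged.

## From modeled rates to complete life tables

`boundary_adjust()` extends modeled rates (35-84) to ages 0-99 by
keeping the modeled *level* at the anchor ages and borrowing the
reference table's age *shape* outside them:

```
m(a) = m(35) * m_ref(a) / m_ref(35),  a < 35
m(a) = m(84) * m_ref(a) / m_ref(84),  a > 84
```

One scale decision matters here: reference tables are stored as annual
death probabilities `q`, while the model produces rates. The ratio
formula is applied on the *rate* scale — reference `q` values are first
converted by `m = -log(1 - q)`, and the adjusted rates are converted
back with `q = 1 - exp(-m)` (`rate_to_q()`, `q_to_rate()`). Applying one
declared scale end-to-end keeps the adjustment exact under both
readings of the formula's inputs and makes the identity tests
(anchor preservation, exact shape ratios) hold to machine precision.

`build_life_table()` uses radix 100,000, `l_{x+1} = l_x (1 - q_x)`,
`L_x = l_x - 0.5 d_x` (a uniform-deaths `a_x = 0.5` at every age,
including infancy — the infant age shape is inherited from the reference
table, so a separate infant separation factor would add nothing
testable), and closes the table at exact age 99: `life_expectancy()`
returns the temporary expectancy `sum(L_x, x < 99) / l_from_age`, with
no open-ended interval. Under zero mortality this is exactly 99 years;
under `q = 1` it is 0.5; under constant `q` it has a geometric closed
form — all asserted in the tests.

## SES quintile assignment

`assign_quintiles()` ranks counties per year by SES index (ties broken
by county ID, for reproducibility) and cuts the cumulative population
into five 20% bands. A county straddling a band boundary is assigned to
the band containing the *midpoint* of its cumulative-population
interval: deterministic, and each band's population share then deviates
from 20% by at most one county's share. A single county holding all the
population sits at midpoint 0.5 and lands in Q3. Quintiles depend only
on ranks, so any strictly monotone transformation of the index leaves
them unchanged. Anchor-year index values are extended to all years by
per-county linear interpolation, linear extrapolation from the two
nearest anchors outside the span, and constant carry for single-anchor
counties (`interpolate_ses_index()`).

## Survival estimators

All curves live on fixed intervals of `interval_months` (monthly or
annual; annual for 10-year summaries).

* **Expected (Ederer II)**: at the start of each interval, every patient
  still under follow-up contributes their individual probability of
  surviving the interval, read from their matched life table at attained
  age (diagnosis age plus elapsed whole years, capped at 99) and
  calendar year (advanced the same way, clamped to the library's span so
  the last table year carries forward). The conditional means multiply
  into the cumulative curve. This attained-age/attained-year bookkeeping
  is the standard convention; the test suite pins it against an
  independently coded brute-force implementation to 1e-12 on small
  cohorts.
* **Observed**: the actuarial (life-table) estimator with effective
  denominator `n_k - c_k/2` — the registry-software convention — with
  Greenwood standard errors. Chosen over Kaplan-Meier because the whole
  pipeline works on fixed-interval summaries.
* **Relative**: the pointwise observed/expected ratio; may exceed 1. The
  expected curve is treated as fixed when scaling standard errors.
* **Cause-specific**: Kaplan-Meier with cancer deaths as events and
  other-cause deaths, study end and the age-99 cap as censorings,
  delegated to `survival::survfit` (Greenwood SEs, log-log intervals).
  Deaths of unknown cause count as non-cancer by default
  (`unknown_as_cancer` flips this), since treating unknowns as events
  would mix background mortality back into the cancer endpoint.

Cohort preparation (`apply_cohort_filters()`) removes autopsy- and
DCO-sourced records and zero-follow-up records, optionally restricts to
single-primary patients, and censors follow-up at the month attained age
reaches 99. `suppress_small_groups()` withholds estimates for groups
under 50 patients at diagnosis (boundary: exactly 50 is reported).
`comparison_table()` differences relative against cause-specific
survival on one-decimal *displayed* values by default, matching how such
tables are published; `displayed = FALSE` differences raw values. The
two modes can disagree by 0.1 in a cell whose inputs were themselves
rounded from finer internals — the test suite documents one such cell in
the shipped published summary.

## What the generator simulates — and what it does not

`true_surface()` expresses the ground truth in the model's own
parameterization: the age effect is the natural cubic spline *through*
log-rate anchors at the age knots (six knots, six anchor values — an
exactly determined interpolation, linear beyond the boundary knots and
hence finite over ages 0-99), calendar time is a linear log-rate trend,
and each quintile adds a main offset and a linear age-interaction slope.
Because truth and model share a basis, `true_coefficients()` maps the
surface onto the exact coefficient vector a correctly specified fit
should recover, and `true_life_expectancy()` gives the exact life
expectancy implied by the surface.

Default conditions, chosen once as a realistic adult mortality regime:
log-rate anchors (-6.5, -6.0, -4.8, -3.7, -3.1, -2.6) at ages
32-82 (rates ~1.5 per 1,000 at 32 to ~74 per 1,000 at 82,
approximately US adult male all-cause mortality), year slope -0.01/yr (a
~1% annual mortality decline), SES offsets (0.4, 0.25, 0.15, 0.05, 0)
for Q1-Q5 with small negative age-interaction slopes (-0.002 to 0) so
the relative SES gradient narrows with age, as it does empirically.
Counties draw one population size per county (uniform in the configured
range) used for all its cells, and quintiles are assigned in balance
across counties. Deaths are Poisson — matching the fitted likelihood —
with draws exceeding the cell population rejected and redrawn, so counts
never exceed exposure.

Cohorts (`generate_cohort()`) draw death times by inverting a
piecewise-constant hazard on annual follow-up segments: background rate
from the matched life table at attained age plus the configured excess
hazard. This is exact under the model and easy to oracle-check. Cause
labels are Bernoulli with probability excess/(excess+background) at the
death segment — the standard competing-risks construction, which makes
cause-specific survival estimable against a known net survival
`exp(-cumulative excess)`. Diagnoses are treated as mid-year, so with
the default 2000-2012 diagnosis years and study end 2012 the maximum
follow-up is 12.5 years, enough to estimate 10-year survival.

The generator deliberately does *not* imitate: real county population
size distributions, infant/childhood mortality humps (the surface is a
smooth adult curve extended linearly in log-rate), migration, cohort
effects, race-specific level differences, or geographic correlation.
Passing recovery tests therefore show the estimators are correct *under
the model*, not that the model captures every feature of registry data.

## Validation experiments and problem sizes

The test suite runs five simulation experiments (sizes chosen to give
the asymptotics room while keeping the default run fast):

* **Coefficient recovery**: 100 replicates of 200 counties with cell
  populations 100,000-200,000 over 1991-2014, grouped at *non-overlapping*
  3-year windows (centers 1992, 1995, ..., 2013). Non-overlapping windows
  keep the Poisson likelihood's independence assumption true, so model
  standard errors are valid and every true coefficient should fall inside
  +/-3 SE with ~99.7% coverage; the suite requires >= 99% over all
  coefficient-replicate pairs. (Overlapping windows, as used for routine
  production of per-year tables, reuse each year's deaths in up to three
  rows; they remain fully supported but would understate SEs in a
  calibration experiment.) Counties sharing a quintile carry identical
  covariates, so the experiment collapses them before fitting — the
  likelihood is unchanged and the suite separately verifies that
  invariance.
* **End-to-end life expectancy**: fitted rates for 2010 are boundary-
  adjusted against the surface's own reference table and must land
  within 0.2 years of `true_life_expectancy()`. Asserted at Q5 and Q3:
  the boundary adjustment transfers the *reference* age shape below 35,
  so a stratum with SES-by-age slope `gamma` carries a known relative
  approximation of `exp((35 - a) * gamma)` there; it vanishes at the
  reference quintile and is negligible at Q3's slope of -0.001.
* **Null calibration**: 100 cohorts of 20,000 with zero excess hazard,
  diagnosed 2000-2002 (so essentially everyone has 10 potential
  follow-up years), matched to their generating table; 5- and 10-year
  relative survival must fall in [0.98, 1.02] in at least 95 runs.
* **Gradient reduction**: two strata with the Q1 and Q5 backgrounds and
  one shared excess hazard (0.03/yr), 80,000 patients each, diagnosed at
  ages 60-70. With stratum-matched tables the 10-year relative-survival
  gap must stay under 1 point; with a pooled-average table the low-SES
  stratum must fall at least 2 points below the high-SES stratum — the
  central mechanism by which an average life table manufactures spurious
  SES survival differences.
* **Ederer II equivalence**: every curve on cohorts of 1-5 patients over
  a three-stratum library equals a brute-force reimplementation to
  1e-12.

`scripts/acceptance.R` reruns the pipeline and experiments at similar
sizes from a single seed and writes the resulting quantities as JSON.

## Known limitations

No overdispersion or spatial random effects (county heterogeneity beyond
SES enters only through the Poisson likelihood); no Ederer I, Hakulinen
or Pohar Perme estimators; no age-standardization of survival; no
cohort-generation life tables; reference tables are taken as given and
never smoothed. The SES index itself is an input — its construction
(factor analysis of census measures) is out of scope.
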