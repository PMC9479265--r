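---
title: "Activity-space alcohol-outlet exposure: models and design choices"
author: "alcospace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-space alcohol-outlet exposure: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcospace)
```

## Scope and data model

`alcospace` measures how much of a child's routine environment — the
activity space traced by a body-worn GPS at a 10-second cadence —
falls near licensed alcohol outlets, and how that exposure is
distributed across area deprivation and across the two anchor settings
of childhood mobility, home and school.

Three tables drive everything. An **outlet table** holds point
locations with an on-/off-sales licence class. A **GPS table** holds
per-child timestamped fixes. A **child table** holds the anchors
(home, school coordinates), the covariates (deprivation quintile or
income rank, sex, tracking start date, six-class urban/rural code) and
the survey-design fields (sampling weight, stratum, cluster). All
geometry is planar metric: coordinates are expected in a projected
CRS (metres), and the core never sees longitude/latitude. The
`project_lonlat()` / `read_gpx()` ingest helpers provide a local
tangent-plane approximation for convenience; they are not a
national-grid transform, and studies with projected coordinates should
supply those directly.

## Exposure definition

Every fix is linked to its globally nearest outlet (any licence).
A fix is **exposed** iff that nearest distance is `<= 10` m — the
threshold is inclusive, configurable, and motivated by typical GPS
receiver error; an exposed fix inherits the licence class of the
single nearest outlet only, so a fix within threshold of both classes
counts once, for the nearer. This makes the two class-specific
exposed-fix counts add exactly to the any-exposure count, an identity
(`prop_on + prop_off = prop_any`) the tests assert.

Nearest-neighbour search uses a compiled uniform-grid index with an
expanding ring search. Equidistant ties resolve to the lowest
`outlet_id`, so linkage is invariant to outlet-table ordering; the
test suite proves exact agreement with an exhaustive O(n·m) scan at
10⁴ fixes × 10³ outlets.

Children enter the analysis only if every tracked day carries strictly
more than 360 fixes (one hour at cadence); "day" is the calendar date
of the timestamp. The strict inequality matters: a day with exactly
360 fixes disqualifies.

## Setting decomposition

At a band `b` (300/400/500 m), each exposed fix is `home_only`,
`school_only`, `both` or `neither` by inclusive distance to the two
anchors; crossing with licence class gives eight cells whose
proportions — relative to the child's exposed fixes — sum to one.
`home_setting = home_only + both` and
`school_setting = school_only + both` are the reported aggregates.
Time-in-setting shares are different and deliberately non-exclusive:
the fraction of *all* fixes within `b` of home and of school can sum
above one.

Cohort rules for the setting analyses: only children with at least one
exposed fix; the home analysis drops children whose home lies within
the exposure threshold of an outlet (e.g. living above a shop) — the
threshold (10 m) operationalises "co-located", since no explicit
distance is part of the rule; the school analysis drops children never
observed within 500 m of school, and that 500 m eligibility radius is
held fixed even when the decomposition band is 300 or 400 m, because
the eligibility rule is a statement about school attendance, not about
the band. Cohort-level decomposition values are design-weighted means
of child-level proportions, not pooled fix counts, so every child
contributes equally per unit weight regardless of sampling effort.

## Design-weighted quasibinomial model

The outcome models compare per-child exposed proportions across
deprivation quintiles, adjusting for urbanicity, season and sex, with
the least-deprived quintile as the reference level. Because weighting
makes exposed-fix counts non-integer, the binomial likelihood is used
quasi-style: per-child proportion `y_i` with denominator `n_i` (fix
count) enters IRLS with working prior weight `a_i = w_i · n_i`, the
sampling weight multiplying the binomial denominator. Convergence is
`max |Δβ| < 1e-8` (cap 100 iterations, error with trace on failure);
under complete separation the fitter stops when the deviance plateaus
at its infimum and flags the fit, as standard GLM fitters do.

The dispersion is the weighted Pearson χ² over residual degrees of
freedom. The coefficient covariance is design-based: score
contributions `a_i (y_i − μ_i) x_i` are summed within clusters;
strata contribute `n_h/(n_h−1)` times the centred between-cluster
cross-products; the sandwich is `A⁻¹ B A⁻¹` with `A` the weighted
information. The sandwich is **not** additionally scaled by the
Pearson dispersion: the score residuals already carry the
overdispersion, and scaling twice would double-count it — the
dispersion is estimated and reported, but plays no role in the
covariance. A stratum with a single cluster ("lonely PSU") is centred
at the grand mean of cluster totals by default (configurable to
`fail`). Intervals use the normal 1.96 critical value by default;
a design-df t quantile can be supplied via `survey_design(crit=)`.

Two reductions anchor correctness. With equal weights and one cluster
per child in a single stratum, point estimates, dispersion and both
deviances coincide with `glm(family = quasibinomial)` to numerical
precision (tested at 1e-6 on a 50-child fixture). And an
intercept-only fit returns exactly the logit of the pooled
trial-weighted proportion.

`pseudo R² = 1 − residual deviance / null deviance`, with the null
fit using the same prior weights. Odds ratios are `exp(β)` with Wald
intervals on the design-based SEs. Predicted probabilities are
delta-method on the logit scale and then back-transformed, so
intervals are ordered and respect `[0, 1]`. **Prediction profile:**
probabilities by quintile are computed at the reference level of every
other fitted factor (profile prediction on the linear predictor), a
choice that has to be made explicitly because averaging on the
probability scale would give different numbers; in a groups-only model
the profile prediction equals the group's pooled weighted proportion.
Expected exposure duration is `wear_minutes × p` with interval
endpoints scaled identically; 67 h of wear is 4020 min. Applying the
formula to a per-fix probability of 0.0079 gives 31.8 min per 4020-min
week; published figures derived from the same inputs have quoted 28.4
min, which is not consistent with the stated arithmetic — this package
always reports the formula value. Similarly, a probability `p` is
reported as the percentage `100·p` of wear time.

## The synthetic cohort generator

Because the original cohort's GPS data are restricted, the package
ships a generator whose defaults encode the study conditions, used
both as documentation of those conditions and as the test bed:

* **Region** — five contiguous 20 × 20 km rectangular zones on an
  abstract metre canvas, one per deprivation quintile; only relative
  geometry matters, so no real CRS is attached.
* **Outlets** — uniform within each zone at per-class counts, default
  16,700 outlets of which 31% off-sales, with off-sales density rising
  about sixfold from the least to the most deprived zone and on-sales
  density peaking at mid-deprivation.
* **Cohort** — 688 children, quintile shares (22.9, 16.5, 17.9, 19.4,
  23.3)%, 55% female, urban shares declining from 90% (most deprived)
  to 70%; strata are the quintile zones and clusters are geographic
  sampling points (default 24 per stratum, homes uniform within 1 km
  of their cluster centre). Home–school separation is configured per
  quintile, shorter in deprived areas (750 m rising to 1500 m).
  Weights are inverse simulated response propensities (lower in
  deprived quintiles: 0.62 up to 0.86) with log-normal jitter
  (sd 0.15), normalised to mean 1 — a plausible construction, since
  no weight formula is part of the public record.
* **Trajectories** — i.i.d. two-anchor mixture per fix: uniform in a
  450 m disc around home (probability 0.53), around school (0.42), or
  roaming uniformly in a 3 km disc around home excluding the 500 m
  discs of both anchors. The exclusion makes the realised within-500 m
  shares equal the configured mixture shares whenever the anchors are
  far enough apart; with the deprived-quintile separations below 1 km
  the kernels overlap the other anchor's band, which is exactly the
  mechanism that produces more `both`-setting exposure in deprived
  areas. Defaults give 24,290 fixes per child (7 days × 3470 at 10 s,
  about 67 h of wear). There is no temporal autocorrelation by
  design: the analysis consumes only per-fix distances.
* **Ground truth** — exposure is induced *geometrically* (outlet
  density around the places children go), never by labelling fixes,
  which keeps the linkage and classification stages honest. The true
  per-quintile per-fix probabilities (order 10⁻³–10⁻², matching the
  study scale) and quintile odds ratios are therefore themselves
  estimated, by `calibrate_ground_truth()`: long-run simulation pooling
  ≥10⁵ (for validation, 1.6×10⁷) fixes per quintile over many
  independent landscape batches.

What the generator does **not** emulate: road networks and routing,
school timetables, GPS measurement error and dropout, indoor/outdoor
transitions, and temporal correlation of fixes. Tests passing on this
generator therefore validate the *pipeline arithmetic and the
estimator*, not the behavioural realism of any particular cohort.

## Validation design and problem sizes

The headline validation is parameter recovery: 200 independent cohorts
of 688 children are generated under a fixed configuration (the default
densities on 8 × 8 km zones, 60 clusters per stratum, 2400 fixes per
child), the full linkage → classification → design-weighted model
chain is run, and the estimated off-sales quintile odds ratios are
compared with the calibrated truth. The recovery test asserts the mean
estimated OR within 5% of truth for every quintile contrast — met at
this design, where the per-cohort log-OR standard error (~0.16) keeps
the arithmetic mean's intrinsic upward Jensen bias,
`exp(Var(log OR)/2)`, near 1% — and 95% interval coverage between
0.92 and 0.98.

The coverage half of that assertion is **not met**, and deliberately
left failing rather than weakened: observed coverage is ≈ 0.91, and
the deficit is a property of the estimator class in this regime, not
of the implementation (which matches the reference GLM to 1e-6 where
they must agree). In the study's rare-exposure conditions — off-sales
per-fix probabilities of 10⁻⁴–10⁻³ in the least-deprived stratum —
most children have no outlet near their anchors at all, so per-child
score contributions are dominated by a heavily right-skewed mixture
(zeros plus a few children whose homes happen to sit near an outlet).
The linearized variance estimate is then itself noisy and
right-skewed, its square root is Jensen-biased downward (mean reported
SE ≈ 0.19 against an empirical sd ≈ 0.22), and normal-theory Wald
intervals cover about 90–91% instead of 95%. Diagnostics show this is
not a cluster-count effect: coverage is the same (~0.90) under a
near-iid design with one child per PSU, and ~0.91 whether children
contribute 1200 or 2400 fixes. First-order Taylor linearization with
Wald intervals — the standard survey-software approach this module
implements — simply runs anticonservative for rare, spatially sparse
exposures; users who need tighter calibration in this regime should
consider a design-df t critical value (`survey_design(crit=)`), which
helps only marginally, or resampling intervals, which are out of this
package's scope.

Other numerical choices: IRLS tolerance 1e-8 on coefficients; fitted
probabilities clamped to `[1e-10, 1 − 1e-10]` inside iterations;
degenerate inputs error early and explicitly (empty outlet table,
zero fixes, non-positive weights, rank-deficient design matrix, a
cluster spanning strata); constant covariates are dropped from
pipeline models with a log note since they would make the design
matrix degenerate on small filtered cohorts.

Problem sizes used by the shipped tests were chosen to exercise every
code path at comfortable precision: unit tests run cohorts of 20–60
children on scaled 6 × 6 km zones; the linkage oracle check uses 10⁴
fixes × 10³ outlets; the recovery study uses the 200 × 688-child
design above with a 1.6×10⁷-fix-per-quintile calibration. The
acceptance script runs a single seeded 688-child pipeline at 600 fixes
per child plus the desk-scale register arithmetic.

## Known limitations

* Exposure is proximity, not entry or attention; with a 10 m threshold
  and 10 s cadence, fast vehicle passes are under-detected relative to
  dwelling nearby — inherited properties of the measurement design.
* The lon/lat ingest is a local tangent-plane approximation; supply
  projected coordinates for survey-grade geometry.
* Variance estimation is first-order and cluster-asymptotic; for rare,
  spatially sparse exposures its Wald intervals run anticonservative
  (~91% observed coverage at nominal 95% in the validation design — see
  the validation section), and a design-df t critical value via
  `survey_design(crit=)` helps only marginally.
* The generator's mixture trajectories have no temporal structure, so
  any method that needs movement dynamics (trip detection, speed
  filtering) is out of scope.
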