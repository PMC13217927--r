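---
title: "Modelling heat-attributable hospital admissions and costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heat-attributable hospital admissions and costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatcost)
```

## The problem

Hot days raise hospital admission rates for a wide range of conditions —
endocrine and metabolic disorders, urinary disease, infections, COPD, skin
conditions — with the elderly and children most affected. `heatcost`
implements a complete pipeline for quantifying that burden in money terms:
it estimates temperature–admission associations from daily panel data,
converts the excess risk on hot days into attributable admissions and
DRG-based costs, and projects both under combined climate and demographic
scenarios. Because the hospital records such analyses rely on are
access-restricted, the package ships a synthetic-data generator with known
ground truth that emulates every input; all tests run against that
generator.

## Two-stage estimation

**First stage.** For each canton × disease group × age group stratum the
daily admission count $y_t$ is modelled by quasi-Poisson regression

$$\log \mathbb{E}[y_t] = \alpha + \mathrm{cb}(T_{max,t}) + \mathrm{dow}_t +
\mathrm{month}_t + \mathrm{holiday}_t\ (+\ \mathrm{year}_t),$$

where $\mathrm{cb}(\cdot)$ is a bi-dimensional cross-basis: a quadratic
B-spline in temperature (knots at the minimum, median and maximum of the
pooled year-round daily-maximum distribution) crossed with a natural cubic
spline over lags 0–7 days (two internal knots equally spaced on the
$\log(\mathrm{lag}+1)$ scale, i.e. at lags 1 and 3; the lag basis keeps an
intercept column, the exposure basis is centred and intercept-free — the
standard identifiable parameterisation). Row $t$, column $(j,k)$ of the
cross-basis holds $\sum_{l=0}^{7} B_j(T_{t-l})\,C_k(l)$ with $B$ centred at
the reference temperature. The model equation lists day-of-week, month and
holiday terms; because long-term trends must also be controlled, calendar-year
indicators are added by default (`year_dummies` toggle). The month term is
month-of-year (11 indicators); an interpretation as month-within-year would
duplicate the year indicators' role and inflate the design, so it was not
adopted. Fitting uses iteratively reweighted least squares (relative deviance
tolerance $10^{-8}$, at most 100 iterations), dispersion $\hat\phi$ =
Pearson $\chi^2$ / residual d.f., coefficient covariance
$\hat\phi (X'WX)^{-1}$. The leading seven days (incomplete lag window) are
dropped from the likelihood rather than padded.

The fitted surface is reduced to the *cumulative* exposure–response: with
lag-basis column sums $s_k = \sum_l C_k(l)$, the reduced coefficients are
$\theta_j = \sum_k \eta_{jk} s_k$ and their covariance follows by the same
linear map. The cumulative log relative risk is exactly zero at the
reference temperature — the pooled warm-season (May–September) median of
daily maximum temperature, the "typical warm day" against which heat excess
is measured.

**Second stage.** Per disease group, the stratum coefficient vectors are
pooled by multivariate meta-regression: age groups as fixed effects on every
basis coefficient, a canton-level random effect shared across the canton's
strata with unstructured between-canton covariance $\Psi$, and two cantonal
meta-predictors (warm-season median temperature; total hospitalisations,
entered as log10; both mean-centred for scale stability — predictions are
invariant to affine predictor rescaling). Estimation is restricted maximum
likelihood with fixed effects profiled out by generalised least squares and
$\Psi$ parameterised through its Cholesky factor; a diagonal $\Psi$ is the
fallback when the unstructured optimisation fails. The random effect applies
to the full coefficient vector — the least structured reading of
"cantons as random effects" — so shrinkage acts on the whole curve shape.
Best linear unbiased predictions are the empirical-Bayes conditional means
$\theta^\ast = X\hat\beta + \Psi Z'(Z\Psi Z' + S)^{-1}(\theta - X\hat\beta)$;
with diagonal $\Psi$ and $S$ every component of $\theta^\ast$ lies between
the stratum estimate and the fixed-effect prediction. Strata excluded by the
minimum-observation rule (below) are simply absent from the design; the
pooled model uses whatever subset of the 6 × 3 layout survives.

## From curves to money

Relative risk at temperature $t$ is $RR(t) = \exp(\theta\cdot[B(t)-B(t_{ref})])$.
Beyond a stratum's historical maximum the log-RR continues linearly with the
spline's end slope for 5 °C and is constant beyond — extrapolation into
unobserved heat is deliberately conservative. Heat-exposed days are days with
maximum temperature *strictly* above the threshold (historically the pooled
warm-season median, 23.3 °C in the emulated sample; future paths count all
days above it regardless of season). For a period,

* $AF = (RR-1)/RR$ from the average RR over exposure days,
* $AN = a \times AF$ with $a$ the recorded exposure-day admissions,
* cost $= AN \times$ unit cost, where the unit cost is the DRG cost weight
  of the (year, disease group, age group) cell times the cantonal base rate
  (hospital rates averaged per canton, then a five-year trailing mean),
  frozen at final-reference-year tariffs.

Annual values are aggregated as the mean over the reference decade
(2013–2022 by default). Because yearly means of ratios are not ratios of
means, the period record stores mean-annual $a$ and $AN$ and *derives*
$AF = AN/a$ and $RR = 1/(1-AF)$, so the record identities hold exactly.
Projections factorise as
$AN = AF \times h_{ref} \times growth \times freq$: the attributable
fraction over a climate path's exposure days in the target decade
(extrapolated curve, vulnerability frozen at historical estimates),
reference-period mean annual exposure-day admissions, the age-specific
population growth factor, and the ratio of projected to reference mean
annual exposure days. The frequency ratio is computed per canton-path —
exposure days are canton-level quantities even though the factorisation
subscripts it by scenario only. At the scenario level AF and freq are
ensemble means and AN is their exact product. The climate-only
counterfactual fixes all growth factors at 1.

Uncertainty is propagated by Monte Carlo: 500 multivariate-normal draws of
the BLUP coefficients per stratum (seeds derived per stratum from one master
seed), percentile 2.5/97.5 intervals for every downstream statistic —
empirical rather than delta-method intervals, and the same draws are reused
across attribution and projection so cost intervals reflect one coherent
coefficient uncertainty. Historical intervals sample the BLUP covariance
(fixed-effect uncertainty plus conditional random-effect covariance), not
the first-stage covariance.

## The synthetic data generator

The generator defines the study conditions and is not tuned per test:

* **Temperature**: sinusoidal annual cycle (mean ≈ 14–16.5 °C across the six
  cantons, amplitude 10 °C, peak mid-July) plus stationary AR(1) Gaussian
  noise (s.d. 3 °C, lag-1 correlation 0.6) — the minimal model that yields
  realistic multi-day hot spells and a warm-season median near 23 °C.
* **Admissions**: log-rate = log baseline + piecewise-linear cumulative
  effect (slope per °C above the reference, zero below, spread over lags 0–7
  by non-negative weights summing to one) + multiplicative day-of-week,
  month and holiday factors. Overdispersion is realised as a gamma-Poisson
  (negative binomial) mixture matching the quasi-Poisson moments
  $\mathrm{Var} = \phi\,\mu$; the quasi-likelihood specifies only moments,
  so a concrete sampler had to be chosen. Default slopes (≈0.01–0.03 per °C)
  give RRs of roughly 1.05–1.15 five degrees above the reference, matching
  the magnitudes reported for moderately heat-sensitive disease groups.
* **Costs**: cost weights uniform on 0.4–2.4 (the span from cheap ear/mental
  treatments to expensive neoplasm care) and cantonal base rates uniform on
  CHF 9,500–11,200, constant over years as Swiss tariffs have been.
* **Climate ensembles**: the historical generator extended to 2023–2074 with
  a linear warm-season ramp reaching 0 / +1.2 / +2.6 °C by 2070 for the low,
  moderate and high pathways (held constant after 2070), ensemble sizes
  12 / 25 / 31, and a small per-path mean offset for inter-model spread.
* **Demographics**: growth factors $(1+r)^{y-2018}$ anchored at 1 in the
  reference-decade midpoint year, with annual rates chosen so the 75+ group
  grows under every pathway, the younger groups are stable or declining
  under the low/moderate pathways and all groups grow under the high one.

What the generator does **not** emulate: station siting and microclimate
(urban heat islands), humidity and air-pollution co-stressors, bias
adjustment of climate models, DRG grouper logic at case level, or
heat-driven changes in calendar patterns. Passing tests therefore
demonstrate the statistical machinery, not fidelity to any particular city's
data.

## Numerical choices and edge cases

* ICD-10 ranges are matched on normalised codes (letter, two digits,
  optional subcode) with prefix-inclusive endpoints, the conventional
  reading of printed ranges. The endocrine range is written E00–E10 in
  common summaries yet diabetes is E10–E14 and the groups are mutually
  exclusive; specific-over-general resolves the overlap, so E10 is diabetes
  and the endocrine group is effectively E00–E09 plus E15–E99. The same
  rule puts the Alzheimer's G-code ranges above the nervous-system chapter
  and COPD above respiratory.
* Strata with fewer than 100 admissions over the whole period are excluded
  before fitting.
* Exposure-basis evaluation outside the knot span continues linearly with
  the boundary slope (relevant only for extrapolated prediction; fitting
  data lie inside the span by construction).
* Covariances are symmetrised and, where a non-PSD matrix arises from
  round-off, repaired to the nearest PSD matrix with a warning before
  sampling.
* Singular within-stratum covariances in the meta-regression are
  ridge-regularised with a warning; collinear meta-regression columns (e.g.
  two centred predictors over only two cantons) are dropped with a warning.
* Degenerate inputs error early and name the offending quantity: empty year
  ranges, negative lag weights, zero-count strata, rank-deficient designs,
  missing cost-table keys, missing upstream pipeline artifacts.

## Known limitation: recovery bias of the quadratic exposure spline

The generator's true cumulative log-RR is piecewise linear — exactly zero
below the reference temperature with a kink there. The estimating basis is a
$C^1$ quadratic spline whose single interior knot sits at the *year-round*
median, about 7 °C below the warm-season-median reference. No function in
that basis can reproduce a derivative discontinuity at the reference, so the
projection of the hinge onto the model space is systematically flattened:
in the deterministic limit (fitting expected counts directly) the cumulative
log-RR five degrees above the reference is underestimated by roughly 20–35%
across realistic temperature configurations. Replacing the exposure basis
with a degree-1 spline with a knot at the reference recovers the truth
exactly, confirming the machinery and isolating the cause as basis
mis-specification. Consequences measured by the test suite: pooled estimates
sit ≈25% below the hinge truth, far outside the narrow BLUP intervals, so
the strict interval-coverage recovery test fails and is reported as failing.
The null case (zero slope, which *is* representable) is correctly
calibrated, and all oracle-equivalence and identity checks pass at
$10^{-9}$ or tighter. Users fitting data believed to have threshold-like
responses should add exposure-basis flexibility near the threshold rather
than rely on the default knot placement.

## Problem sizes used by the test suite

Unit tests run on toy series (tens of days) and short panels (10 years).
The recovery study uses 50 replicates of the full 6-canton × 3-age design
with 30-year series; null calibration uses 25 replicates of 10-year series;
the meta-regression recovery study uses 100 simulated 6 × 3 designs with
$k = 2$; projection checks use 2–3-path ensembles. The acceptance script
uses 10 recovery replicates on 15-year series and 5 null replicates — sizes
chosen to estimate each operating characteristic to usefully small Monte
Carlo error on a single CPU.

## Interpreting the baseline-robustness check

Projected absolute costs are nearly invariant to the reference decade:
the attributable number factorises so the reference enters only through
admissions *per exposure day*, which is stable across overlapping decades.
The reported *percent* change also divides by the reference-period cost,
which does fluctuate with decade-specific weather; the robustness check
therefore compares projected totals and projected cost *increases* (CHF
amounts) across overlapping reference decades, the quantities the
projection method actually stabilises.
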