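# heatcost

Quantifying the hospital burden of heat — admissions and their costs, now
and under future climate and demographic scenarios.

`heatcost` is for environmental epidemiologists and health economists who
need to turn daily panel data (admission counts and maximum temperature per
region × disease group × age group) into heat-attributable admission counts
and CHF amounts, and to project those forward. The raw hospital records
behind such analyses are typically access-restricted, so the package ships a
synthetic-data generator with known ground truth that emulates every input;
the whole pipeline is developed and tested against it.

## The model

Stage one fits, per stratum, a distributed lag non-linear model by
quasi-Poisson regression:

    log E[y_t] = α + cb(Tmax_t) + dow + month + holiday (+ year)

where `cb(·)` is the cross-basis of a centred quadratic B-spline in
temperature (knots at the minimum, median and maximum of the pooled
year-round distribution) and a natural cubic spline over lags 0–7 days.
The fitted surface is reduced to a cumulative exposure–response curve
`θ` centred at the reference temperature (the pooled warm-season median).
Stage two pools the stratum curves per disease group by multivariate
meta-regression (REML): age fixed effects, canton random effects with
unstructured between-canton covariance, cantonal meta-predictors; best
linear unbiased predictions (BLUPs) shrink noisy cantonal curves toward the
pooled mean.

Attribution on heat-exposed days (Tmax strictly above the threshold):

    RR   = exp(θ·[B(t) − B(t_ref)])     averaged over exposure days
    AF   = (RR − 1)/RR
    AN   = a × AF                        a = exposure-day admissions
    cost = AN × cost weight × base rate

Projections to 2023–2074 factorise as
`AN = AF × h_ref × growth × freq` (reference exposure-day admissions,
age-specific population growth, exposure-day frequency ratio), with a
climate-only counterfactual (`growth ≡ 1`) and 500-draw Monte Carlo
percentile intervals throughout.

## Worked example

```r
library(heatcost)

# synthetic study: one canton, 10 years, known truth
sc    <- sim_config(cantons = "ZH", years = 2013:2022, seed = 42)
temps <- gen_temperature(sc, "ZH")
thr   <- warm_season_threshold(temps)          # heat threshold, deg C
truth <- true_surface(ref_temp = thr, log_rr_slope = 0.02,
                      baseline_rate = 25, dispersion = 1.5)
adm   <- gen_admissions(temps, truth, seed = 7)

spec  <- basis_spec_from_data(temps, ref_temp = thr)
fit   <- fit_stratum(stratum_series(temps, adm, "ZH", "urinary", "75+"), spec)
curve <- reduce_cumulative(fit)

rr_at(curve, thr + 5)
rec <- attribute_period(curve, temps, adm, unit_cost = 12000,
                        years = 2013:2022, threshold = thr)
rec[c("rr", "af", "a", "an", "cost")]
```

Output from this exact script:

```
         t       rr     rr_lo    rr_hi
1 26.58215 1.036466 0.9981061 1.076299
       rr         af      a       an     cost
1 1.02254 0.02204331 2063.4 45.48416 545809.9
```

The estimated relative risk five degrees above the warm-season median is
about 1.04, below the generating truth of e^0.1 ≈ 1.105: the quadratic
exposure spline flattens the piecewise-linear truth substantially (a known
limitation analysed in the methods vignette). On average 2,063 admissions
per year fall on heat-exposed days; the period-effective attributable
fraction of 2.2% yields ≈45 heat-attributable admissions and ≈CHF 546,000
per year at a CHF 12,000 unit cost.

The full pipeline is also runnable step by step (`simulate`, `fit`, `pool`,
`attribute`, `project`, `report`) via `run_subcommand()` on a configuration
list (`default_config()`), or from a shell through
`inst/cli/heatcost.R`.

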