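Package: heatcost
Title: Heat-Attributable Hospital Admissions and Costs Under Climate Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage time-series modelling of the association between daily
    maximum temperature and hospital admissions: first-stage distributed lag
    non-linear models (quadratic B-spline exposure basis crossed with a natural
    cubic lag basis) fitted by quasi-Poisson regression per canton, disease
    group and age group; second-stage multivariate meta-regression with age
    fixed effects and cantonal random effects, yielding best linear unbiased
    predictions of the cumulative exposure-response. Attributable fractions on
    heat-exposed days are converted to hospital costs through diagnosis-related
    group (DRG) cost weights and cantonal base rates, and projected to 2023-2074
    under combined climate and demographic scenarios with Monte Carlo
    uncertainty propagation. A synthetic-data generator with known ground truth
    emulates every input, so the full pipeline is testable without restricted
    hospital records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, splines, utils, tools, yaml
Suggests: testthat (>= 3.0.0), jsonlite, metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
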