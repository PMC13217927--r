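# Shared fixtures, all built in code.

# Daily temperature frame with arbitrary values.
make_temps <- function(tmax, start = "2010-01-01", canton = "ZH") {
  data.frame(date = seq(as.Date(start), by = "day", length.out = length(tmax)),
             canton = canton, tmax_c = tmax, stringsAsFactors = FALSE)
}

# Constant-temperature frame covering whole years.
const_temps <- function(value, years = 2010:2012, canton = "ZH") {
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  data.frame(date = dates, canton = canton, tmax_c = value,
             stringsAsFactors = FALSE)
}

toy_spec <- function(ref = 23) basis_spec(c(0, 15, 35), ref_temp = ref)

# A reduced curve with chosen coefficients on the toy basis.
make_curve <- function(coef = c(0.2, 0.35, 0.5), vcov = diag(1e-4, 3),
                       spec = toy_spec(), hist_max = 30, canton = "ZH",
                       disease_group = "dg", age_group = "15-74") {
  reduced_curve(coef = coef, vcov = vcov, spec = spec, hist_max = hist_max,
                canton = canton, disease_group = disease_group,
                age_group = age_group)
}

flat_curve <- function(...) make_curve(coef = c(0, 0, 0), ...)

# Small but complete pipeline configuration (2 cantons x 2 diseases x 2 ages,
# 10 years) used by the end-to-end fixture tests.
small_config <- function(seed = 7) {
  cfg <- default_config(seed = seed)
  cfg$cantons <- c("BE", "ZH")
  cfg$years <- c(2013, 2022)
  cfg$diseases <- list(
    heatsens = list(slope = 0.02, baseline = 12, dispersion = 1.3),
    nullgrp  = list(slope = 0.00, baseline = 15, dispersion = 1.3))
  cfg$age_multipliers <- c("15-74" = 1, "75+" = 0.6)
  cfg$growth_rates <- list(
    low  = c("15-74" = -0.001, "75+" = 0.020),
    high = c("15-74" =  0.010, "75+" = 0.028))
  cfg$scenarios <- list(low = list(ramp = 0, n_sim = 2),
                        high = list(ramp = 2.6, n_sim = 2))
  cfg$projection_years <- c(2023, 2069)
  cfg$decades <- list(c(2060, 2069))
  cfg$n_draws <- 100
  cfg
}

# First-stage fit object with chosen cross-basis coefficients, bypassing
# estimation (for reduction-map tests).
fake_fit <- function(eta, spec = toy_spec(), seed = 1) {
  J <- 3; K <- 4
  stopifnot(length(eta) == J * K)
  nm <- paste0("cb", colnames(build_crossbasis(rep(spec$ref_temp, 10), spec)))
  cf <- c("(Intercept)" = 0, stats::setNames(eta, nm))
  set.seed(seed)
  A <- matrix(rnorm((J * K + 1)^2), J * K + 1)
  V <- crossprod(A) * 1e-6
  structure(list(coef = cf, vcov = V, dispersion = 1,
                 eta_index = 1 + seq_len(J * K), spec = spec, J = J, K = K,
                 hist_max = 30, canton = "ZH", disease_group = "dg",
                 age_group = "15-74"),
            class = "first_stage_fit")
}
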