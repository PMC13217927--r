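# Generators: determinism, configured moments, scenario structure.

test_that("zero-noise temperature is a deterministic sinusoid with the configured extremes", {
  sc <- sim_config(cantons = "ZH", years = 2010:2012, seed = 1,
                   temperature_params = list(
                     ZH = list(mean = 15, amplitude = 10, sd = 0, ar = 0)))
  t1 <- gen_temperature(sc, "ZH")
  t2 <- gen_temperature(sc, "ZH")
  expect_identical(t1, t2)
  expect_equal(max(t1$tmax_c), 25, tolerance = 1e-2)
  expect_equal(min(t1$tmax_c), 5, tolerance = 1e-2)
  expect_equal(mean(t1$tmax_c), 15, tolerance = 0.1)
  expect_equal(nrow(t1), as.integer(as.Date("2012-12-31") -
                                      as.Date("2010-01-01")) + 1L)
})

test_that("temperature generator is seed-reproducible and mean-accurate over 30 years", {
  sc <- sim_config(cantons = "ZH", years = 1991:2020, seed = 1,
                   temperature_params = list(
                     ZH = list(mean = 15, amplitude = 10, sd = 3, ar = 0.6)))
  t1 <- gen_temperature(sc, "ZH")
  expect_identical(t1, gen_temperature(sc, "ZH"))
  # AR(1) noise: sd of the mean is sd*sqrt((1+ar)/(1-ar))/sqrt(n)
  n <- nrow(t1)
  bound <- 3 * 3 * sqrt((1 + 0.6) / (1 - 0.6)) / sqrt(n)
  expect_lt(abs(mean(t1$tmax_c) - 15), bound)
  expect_error(gen_temperature(sim_config(years = 2020, cantons = "ZH")),
               "2 full calendar years")
  expect_error(gen_temperature(sc, "XX"), "unknown canton")
})

test_that("admission counts realise the stated moment structure", {
  truth0 <- true_surface(ref_temp = 23, log_rr_slope = 0, baseline_rate = 20,
                         dispersion = 1)
  temps <- const_temps(23, years = 1800:2073)   # ~1e5 days
  a1 <- gen_admissions(temps, truth0, seed = 3)
  expect_true(all(a1$count >= 0 & a1$count == round(a1$count)))
  expect_equal(var(a1$count) / mean(a1$count), 1, tolerance = 0.05)

  truth2 <- true_surface(ref_temp = 23, log_rr_slope = 0, baseline_rate = 20,
                         dispersion = 2)
  a2 <- gen_admissions(temps, truth2, seed = 3)
  expect_equal(var(a2$count) / mean(a2$count), 2, tolerance = 0.1)

  # closed-form mean: sustained +1 C with slope 0.05 -> baseline * e^0.05
  truth5 <- true_surface(ref_temp = 23, log_rr_slope = 0.05,
                         lag_weights = rep(1 / 8, 8), baseline_rate = 20,
                         dispersion = 1.5)
  a5 <- gen_admissions(const_temps(24, years = 1800:2073), truth5, seed = 4)
  expect_equal(mean(a5$count), 20 * exp(0.05), tolerance = 0.01)

  expect_identical(gen_admissions(temps, truth0, seed = 9),
                   gen_admissions(temps, truth0, seed = 9))
})

test_that("invalid ground-truth surfaces are rejected", {
  expect_error(true_surface(lag_weights = c(-0.1, rep(0.2, 7))),
               "non-negative")
  expect_error(true_surface(lag_weights = rep(1, 5)), "lags 0-7")
  expect_error(true_surface(baseline_rate = 0), "> 0")
  expect_error(true_surface(dispersion = 0.5), ">= 1")
})

test_that("cost tables are deterministic, positive and inside the configured bands", {
  sc <- sim_config(cantons = c("BE", "ZH"), years = 2013:2022, seed = 5)
  ct1 <- gen_cost_tables(sc, disease_groups = c("urinary", "copd"))
  ct2 <- gen_cost_tables(sc, disease_groups = c("urinary", "copd"))
  expect_identical(ct1, ct2)
  expect_true(all(ct1$cost_weight$cost_weight > 0))
  expect_true(all(ct1$cost_weight$cost_weight >= 0.4 &
                    ct1$cost_weight$cost_weight <= 2.4))
  expect_true(all(ct1$base_rate$base_rate >= 9500 &
                    ct1$base_rate$base_rate <= 11200))
})

test_that("climate ensembles have the configured sizes and warming ramps", {
  sc <- sim_config(cantons = "ZH", years = 2013:2022, seed = 11,
                   projection_years = 2023:2069)
  sizes <- vapply(c("low", "moderate", "high"),
                  function(s) sc$scenarios[[s]]$n_sim, numeric(1))
  expect_equal(unname(sizes), c(12, 25, 31))

  sc_small <- sc
  sc_small$scenarios <- list(low = list(ramp = 0, n_sim = 2),
                             high = list(ramp = 2.6, n_sim = 2))
  warm_mean <- function(d, yrs) {
    y <- as.integer(format(d$date, "%Y"))
    w <- d[y %in% yrs & heatcost:::is_warm_season(d$date), ]
    mean(w$tmax_c)
  }
  hist <- gen_temperature(sc_small, "ZH")
  base <- warm_mean(hist, 2013:2022)

  low <- gen_climate_ensemble("low", sc_small)
  expect_length(low, 2)
  # per-path spread: inter-model offset sd 0.3 plus two decadal warm-season
  # noise means (AR(1), sd ~0.15 each) -> statistic sd ~0.36, 3 sigma ~1.1
  for (p in low)
    expect_lt(abs(warm_mean(p, 2060:2069) - base), 1.1)

  high <- gen_climate_ensemble("high", sc_small)
  for (p in high) {
    decadal <- vapply(list(2030:2039, 2040:2049, 2050:2059, 2060:2069),
                      function(dec) warm_mean(p, dec), numeric(1))
    expect_true(all(diff(decadal) > 0))
    expect_equal(warm_mean(p, 2063:2069) - base, 2.6, tolerance = 0.7)
  }
  expect_error(gen_climate_ensemble("rcp9", sc_small), "unknown scenario")
})

test_that("demographic growth factors anchor at 1 and follow the scenario shapes", {
  sc <- sim_config(cantons = "ZH", years = 2013:2022, seed = 1)
  for (scen in c("low", "moderate", "high")) {
    demo <- gen_demographics(scen, sc)
    anchor <- demo[demo$year == 2018, ]
    expect_equal(anchor$growth, rep(1, nrow(anchor)))
    eld <- demo[demo$age_group == "75+", ]
    expect_true(all(diff(eld$growth[order(eld$year)]) >= 0))
  }
  low <- gen_demographics("low", sc)
  expect_true(all(low$growth[low$age_group == "0-14" &
                               low$year >= 2060] < 1))
  expect_error(gen_demographics("nope", sc), "unknown scenario")
})
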