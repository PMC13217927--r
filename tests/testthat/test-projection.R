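# Scenario projections: frequency ratios, the attributable-number
# factorisation, climate-only counterfactual and decadal summaries.

# Reference decade relabelled into a projection decade (identical weather).
shift_years <- function(temps, by = 50) {
  out <- temps
  out$date <- as.Date(sprintf("%04d-%s", as.integer(format(temps$date, "%Y"))
                              + by, format(temps$date, "%m-%d")))
  out[!is.na(out$date), ]
}

test_that("frequency ratio counts exposure days against the reference window", {
  sc <- sim_config(cantons = "ZH", years = 2013:2022, seed = 21)
  ref <- gen_temperature(sc, "ZH")
  path <- shift_years(ref, 50)
  expect_equal(freq_ratio(path, ref, decade = 2063:2072), 1)

  # constructed 150 vs 100 days/yr
  mk <- function(nhot, years) {
    d <- do.call(rbind, lapply(years, function(y) {
      dates <- seq(as.Date(sprintf("%d-01-01", y)), by = "day",
                   length.out = 365)
      data.frame(date = dates, tmax_c = c(rep(30, nhot),
                                          rep(10, 365 - nhot)))
    }))
    d
  }
  expect_equal(freq_ratio(mk(150, 2060:2069), mk(100, 2013:2022),
                          decade = 2060:2069), 1.5)

  # ramped synthetic path matches a brute-force scan
  sc2 <- sim_config(cantons = "ZH", years = 2013:2022, seed = 21,
                    scenarios = list(high = list(ramp = 2.6, n_sim = 1)),
                    projection_years = 2055:2074)
  p <- gen_climate_ensemble("high", sc2)[[1]]
  y <- as.integer(format(p$date, "%Y"))
  brute <- sum(p$tmax_c[y %in% 2060:2069] > 23.3) / 10 /
    (sum(ref$tmax_c > 23.3) / 10)
  expect_equal(freq_ratio(p, ref, 2060:2069), brute, tolerance = 1e-12)
  expect_error(freq_ratio(mk(0, 2060:2069), mk(0, 2013:2022), 2060:2069),
               "zero reference")
})

test_that("projected records factorise exactly and mirror the reference under a null scenario", {
  sc <- sim_config(cantons = "ZH", years = 2013:2022, seed = 3)
  ref <- gen_temperature(sc, "ZH")
  counts <- data.frame(date = ref$date, count = rpois(nrow(ref), 15))
  cu <- make_curve(hist_max = max(ref$tmax_c))
  h <- heatcost:::reference_h(ref, counts, 2013:2022, 23.3)
  ref_rec <- attribute_period(cu, ref, counts, 9000, 2013:2022, 23.3)

  path <- shift_years(ref, 50)
  rec <- project_stratum(cu, list(path), ref, h, growth = 1.4,
                         unit_cost = 9000, decade = 2063:2072,
                         scenario = "test", ref_record = ref_rec)
  expect_equal(rec$an, rec$af * rec$h_ref * rec$growth * rec$freq,
               tolerance = 1e-12)
  expect_equal(rec$cost, rec$an * 9000)

  # identical climate + unit growth reproduces the reference attribution
  # (the projection pools exposure days across the decade, the reference
  # aggregates annually, so agreement is close but not to machine precision)
  rec1 <- project_stratum(cu, list(path), ref, h, growth = 1,
                          unit_cost = 9000, decade = 2063:2072,
                          ref_record = ref_rec)
  expect_equal(rec1$freq, 1)
  expect_equal(rec1$an, ref_rec$an, tolerance = 0.02)
  expect_lt(abs(rec1$pct_change), 2)
})

test_that("climate-only equals the full projection when growth is one, and its share is sensible", {
  sc <- sim_config(cantons = "ZH", years = 2013:2022, seed = 9,
                   scenarios = list(mod = list(ramp = 1.2, n_sim = 2)),
                   projection_years = 2055:2074)
  ref <- gen_temperature(sc, "ZH")
  counts <- data.frame(date = ref$date, count = rpois(nrow(ref), 15))
  cu <- make_curve(hist_max = max(ref$tmax_c))
  h <- heatcost:::reference_h(ref, counts, 2013:2022, 23.3)
  ref_rec <- attribute_period(cu, ref, counts, 9000, 2013:2022, 23.3)
  ens <- lapply(gen_climate_ensemble("mod", sc),
                function(p) p[p$canton == "ZH", ])

  full1 <- project_stratum(cu, ens, ref, h, growth = 1, unit_cost = 9000,
                           decade = 2060:2069, ref_record = ref_rec)
  co <- climate_only(cu, ens, ref, h, unit_cost = 9000,
                     decade = 2060:2069, ref_record = ref_rec)
  expect_equal(co$an, full1$an, tolerance = 1e-12)
  expect_equal(co$cost, full1$cost, tolerance = 1e-12)

  # with warming and aging, the climate-only share of the increase is in (0,1)
  full <- project_stratum(cu, ens, ref, h, growth = 1.6, unit_cost = 9000,
                          decade = 2060:2069, ref_record = ref_rec)
  sh <- climate_share(full, co, ref_rec)
  expect_gt(sh, 0)
  expect_lt(sh, 1)
})

test_that("ordered warming ramps give ordered projected costs under shared growth", {
  sc0 <- sim_config(cantons = "ZH", years = 2013:2022, seed = 15,
                    scenarios = list(low = list(ramp = 0, n_sim = 2),
                                     mod = list(ramp = 1.2, n_sim = 2),
                                     high = list(ramp = 2.6, n_sim = 2)),
                    projection_years = 2055:2074)
  ref <- gen_temperature(sc0, "ZH")
  counts <- data.frame(date = ref$date, count = rpois(nrow(ref), 15))
  cu <- make_curve(hist_max = max(ref$tmax_c))
  h <- heatcost:::reference_h(ref, counts, 2013:2022, 23.3)
  costs <- vapply(c("low", "mod", "high"), function(s) {
    ens <- lapply(gen_climate_ensemble(s, sc0),
                  function(p) p[p$canton == "ZH", ])
    project_stratum(cu, ens, ref, h, growth = 1.3, unit_cost = 9000,
                    decade = 2060:2069, scenario = s)$cost
  }, numeric(1))
  expect_true(costs[["low"]] <= costs[["mod"]] &&
                costs[["mod"]] <= costs[["high"]])
})

test_that("decadal summaries aggregate additively across cantons", {
  rec <- data.frame(scenario = c("high", "high"), decade = "2060-2069",
                    age_group = "75+", canton = c("BE", "ZH"),
                    cost = c(100, 250), cost_ref = c(80, 100),
                    an = c(1, 2), rr = c(1.2, 1.4))
  one <- decadal_summary(rec[1, ])
  expect_equal(one$cost, 100)
  expect_equal(one$pct_change, 25)
  both <- decadal_summary(rec)
  expect_equal(both$cost, 350)
  expect_equal(both$cost_ref, 180)
  expect_equal(both$rr, 1.3)
  expect_equal(both$pct_change, 100 * (350 - 180) / 180)
})
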