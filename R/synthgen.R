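# Synthetic-data generators: temperature, admissions with a known
# exposure-lag surface, DRG-style cost tables, climate ensembles and
# demographic growth factors. Everything downstream of this file can be
# tested against the ground truth these generators encode.

#' Ground-truth exposure-lag surface for simulated admissions
#'
#' Defines the data-generating process for daily admission counts: a baseline
#' rate at the reference temperature, a piecewise-linear log relative risk
#' above it (zero effect below), non-negative lag weights distributing that
#' effect over lags 0-7, a quasi-Poisson overdispersion factor, and
#' multiplicative calendar effects. The piecewise-linear form makes the
#' cumulative log-RR at any temperature analytically known:
#' `log_rr_slope * max(0, t - ref_temp)` for sustained exposure.
#'
#' @param ref_temp reference temperature in degrees C (warm-season median).
#' @param log_rr_slope log relative risk per degree C above `ref_temp` for
#'   sustained (all-lag) exposure.
#' @param lag_weights non-negative weights over lags 0-7; normalised to sum
#'   to 1.
#' @param baseline_rate expected admissions per day at the reference
#'   temperature (must be > 0).
#' @param dispersion overdispersion factor (variance/mean), >= 1.
#' @param dow_effects length-7 multiplicative day-of-week factors (Mon-Sun).
#' @param month_effects length-12 multiplicative month factors.
#' @param holiday_effect multiplicative factor on national holidays.
#' @return An object of class `true_surface`.
#' @export
true_surface <- function(ref_temp = 23.3,
                         log_rr_slope = 0.02,
                         lag_weights = 0.6^(0:7),
                         baseline_rate = 30,
                         dispersion = 1.5,
                         dow_effects = rep(1, 7),
                         month_effects = rep(1, 12),
                         holiday_effect = 1) {
  if (any(lag_weights < 0)) stop("lag_weights must be non-negative")
  if (length(lag_weights) != 8L) stop("lag_weights must cover lags 0-7")
  if (baseline_rate <= 0) stop("baseline_rate must be > 0")
  if (dispersion < 1) stop("dispersion must be >= 1")
  if (length(dow_effects) != 7L || length(month_effects) != 12L)
    stop("dow_effects must have length 7 and month_effects length 12")
  if (any(c(dow_effects, month_effects, holiday_effect) <= 0))
    stop("calendar effects are multiplicative and must be > 0")
  w <- lag_weights / sum(lag_weights)
  structure(list(ref_temp = ref_temp, log_rr_slope = log_rr_slope,
                 lag_weights = w, baseline_rate = baseline_rate,
                 dispersion = dispersion, dow_effects = dow_effects,
                 month_effects = month_effects,
                 holiday_effect = holiday_effect),
            class = "true_surface")
}

#' True cumulative log relative risk at a temperature
#'
#' The analytic value estimated by the pipeline: summed-over-lags log-RR for
#' sustained exposure at `t` relative to the reference temperature.
#' @param truth a [true_surface()].
#' @param t temperature(s), degrees C.
#' @export
true_cum_logrr <- function(truth, t) {
  truth$log_rr_slope * pmax(0, t - truth$ref_temp)
}

#' Simulation configuration
#'
#' Study conditions for the generators: cantons, calendar span, one master
#' seed, per-canton temperature parameters (sinusoidal annual cycle with AR(1)
#' Gaussian noise), climate scenarios (warming ramp reached by 2070 and
#' ensemble size) and demographic growth rates. Defaults emulate the six
#' urban Swiss cantons and the three combined SSP-RCP pathways: warm-season
#' conditions stable under the low pathway, about +1.2 degrees C by 2070
#' under the moderate one and +2.6 degrees C under the high one, with
#' ensembles of 12, 25 and 31 model runs respectively.
#'
#' @param cantons character vector of canton identifiers.
#' @param years inclusive range of historical calendar years.
#' @param seed master integer seed; all generator streams derive from it.
#' @param temperature_params named list per canton with entries `mean`
#'   (annual mean daily maximum, degrees C), `amplitude` (seasonal
#'   half-range), `sd` (stationary noise s.d.), `ar` (lag-1 autocorrelation).
#' @param scenarios named list per scenario with entries `ramp` (degrees C of
#'   warm-season warming reached by 2070) and `n_sim` (ensemble size).
#' @param growth_rates named list per scenario of annual growth rates by age
#'   group (`0-14`, `15-74`, `75+`).
#' @param projection_years inclusive range of projected calendar years.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(cantons = c("BE", "BS", "GE", "TI", "VD", "ZH"),
                       years = 1998:2022,
                       seed = 20220101,
                       temperature_params = NULL,
                       scenarios = list(
                         low      = list(ramp = 0.0, n_sim = 12),
                         moderate = list(ramp = 1.2, n_sim = 25),
                         high     = list(ramp = 2.6, n_sim = 31)),
                       growth_rates = list(
                         low      = c("0-14" = -0.004, "15-74" = -0.001, "75+" = 0.020),
                         moderate = c("0-14" =  0.002, "15-74" =  0.001, "75+" = 0.022),
                         high     = c("0-14" =  0.012, "15-74" =  0.010, "75+" = 0.028)),
                       projection_years = 2023:2074) {
  if (length(years) < 2L) stop("years must span at least 2 full calendar years")
  if (is.null(temperature_params)) {
    base <- c(BE = 14.0, BS = 15.5, GE = 15.2, TI = 16.5, VD = 14.8, ZH = 14.3)
    temperature_params <- lapply(cantons, function(cn) {
      m <- if (cn %in% names(base)) base[[cn]] else 15
      list(mean = m, amplitude = 10, sd = 3, ar = 0.6)
    })
    names(temperature_params) <- cantons
  }
  for (s in scenarios)
    if (is.null(s$n_sim) || s$n_sim < 1) stop("n_simulations must be >= 1")
  structure(list(cantons = cantons, years = years, seed = seed,
                 temperature_params = temperature_params,
                 scenarios = scenarios, growth_rates = growth_rates,
                 projection_years = projection_years),
            class = "sim_config")
}

# Sinusoid + AR(1) daily maximum temperature for an arbitrary date span.
sinusoid_ar1 <- function(dates, mean, amplitude, sd, ar, seed,
                         trend = numeric(length(dates))) {
  doy <- as.integer(format(dates, "%j"))
  cycle <- mean + amplitude * cos(2 * pi * (doy - 200) / 365)
  n <- length(dates)
  noise <- if (sd > 0) {
    with_seed(seed, {
      z <- stats::rnorm(n)
      e <- numeric(n)
      e[1] <- z[1] * sd
      for (t in seq_len(n)[-1]) e[t] <- ar * e[t - 1] + sqrt(1 - ar^2) * sd * z[t]
      e
    })
  } else numeric(n)
  cycle + noise + trend
}

#' Generate a daily maximum temperature series for one canton
#'
#' Seasonal sinusoid (annual mean plus amplitude, peaking in mid-July) with
#' stationary AR(1) Gaussian noise, emulating station observations of daily
#' maximum temperature.
#'
#' @param config a [sim_config()].
#' @param canton canton identifier present in `config`.
#' @return A data.frame with columns `date`, `canton`, `tmax_c`, one row per
#'   calendar day of `config$years`.
#' @export
gen_temperature <- function(config, canton) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$years) < 2L)
    stop("temperature generation needs a year range spanning >= 2 full years")
  p <- config$temperature_params[[canton]]
  if (is.null(p)) stop("unknown canton: ", canton)
  dates <- year_dates(config$years)
  tmax <- sinusoid_ar1(dates, p$mean, p$amplitude, p$sd, p$ar,
                       seed = derive_seed(config$seed, paste0("temp:", canton)))
  data.frame(date = dates, canton = canton, tmax_c = tmax,
             stringsAsFactors = FALSE)
}

#' Simulate daily admission counts from a known surface
#'
#' Expected log-rate at day t is
#' `log(baseline_rate) + sum_l lag_weights[l] * log_rr_slope * max(0, T[t-l] - ref_temp)`
#' plus log day-of-week, month and holiday effects. Overdispersion is realised
#' as a gamma-Poisson mixture (negative binomial) whose first two moments
#' match the quasi-Poisson specification `Var = dispersion * mean`. The first
#' `lag` days of the exposure window reuse the first day's exposure so the
#' returned series is aligned with `temps`; model fitting drops those rows.
#'
#' @param temps data.frame with columns `date` and `tmax_c` (as returned by
#'   [gen_temperature()]).
#' @param truth a [true_surface()].
#' @param seed integer seed.
#' @param holidays Date vector of national holidays; defaults to fixed-date
#'   Swiss holidays within the span of `temps`.
#' @return A data.frame with columns `date`, `count`.
#' @export
gen_admissions <- function(temps, truth, seed, holidays = NULL) {
  stopifnot(inherits(truth, "true_surface"))
  if (any(truth$lag_weights < 0)) stop("lag_weights must be non-negative")
  dates <- temps$date
  yrs <- as.integer(format(range(dates), "%Y"))
  if (is.null(holidays)) holidays <- holiday_dates_default(yrs[1]:yrs[2])
  L <- length(truth$lag_weights) - 1L
  xs <- pmax(0, temps$tmax_c - truth$ref_temp)
  xs_pad <- c(rep(xs[1], L), xs)
  lag_term <- stats::filter(xs_pad, truth$lag_weights, method = "convolution",
                            sides = 1)
  lag_term <- as.numeric(lag_term)[(L + 1L):length(xs_pad)]
  dow <- as.integer(format(dates, "%u"))        # 1 = Monday
  mon <- as.integer(format(dates, "%m"))
  hol <- dates %in% holidays
  log_mu <- log(truth$baseline_rate) +
    truth$log_rr_slope * lag_term +
    log(truth$dow_effects[dow]) + log(truth$month_effects[mon]) +
    ifelse(hol, log(truth$holiday_effect), 0)
  mu <- exp(log_mu)
  counts <- with_seed(seed, {
    if (truth$dispersion == 1) {
      stats::rpois(length(mu), mu)
    } else {
      # NB2 with Var = phi * mu  =>  size = mu / (phi - 1)
      stats::rnbinom(length(mu), mu = mu, size = mu / (truth$dispersion - 1))
    }
  })
  data.frame(date = dates, count = as.integer(counts))
}

#' Generate DRG-style cost tables
#'
#' Cost weights per (disease group, age group) drawn uniformly in a realistic
#' DRG range (0.4-2.4, spanning cheap ear/mental treatments up to expensive
#' neoplasm care) and cantonal base rates uniform in a band around CHF
#' 9,500-11,200, both held constant over years as Swiss tariffs have been.
#'
#' @param config a [sim_config()].
#' @param disease_groups character vector of disease group names; defaults to
#'   the packaged 21-group classification.
#' @param age_groups character vector of age groups.
#' @param weight_range,rate_range uniform sampling bands.
#' @return A list with data.frames `cost_weight` (year, disease_group,
#'   age_group, cost_weight) and `base_rate` (year, canton, base_rate),
#'   wrapped by [cost_table()].
#' @export
gen_cost_tables <- function(config,
                            disease_groups = disease_group_names(),
                            age_groups = c("0-14", "15-74", "75+"),
                            weight_range = c(0.4, 2.4),
                            rate_range = c(9500, 11200)) {
  stopifnot(inherits(config, "sim_config"))
  years <- config$years
  g <- expand.grid(disease_group = disease_groups, age_group = age_groups,
                   stringsAsFactors = FALSE)
  w <- with_seed(derive_seed(config$seed, "costweights"),
                 stats::runif(nrow(g), weight_range[1], weight_range[2]))
  cw <- merge(data.frame(year = years),
              cbind(g, cost_weight = w))
  r <- with_seed(derive_seed(config$seed, "baserates"),
                 stats::runif(length(config$cantons),
                              rate_range[1], rate_range[2]))
  br <- merge(data.frame(year = years),
              data.frame(canton = config$cantons, base_rate = r,
                         stringsAsFactors = FALSE))
  cost_table(cost_weight = cw, base_rate = br)
}

#' Generate an ensemble of projected daily temperature paths
#'
#' Each path extends the historical generator over the projection years and
#' adds a linear warm-season warming ramp reaching the scenario's configured
#' increase by 2070 (held constant afterwards), plus a small per-path offset
#' emulating inter-model spread. Default ensemble sizes are 12, 25 and 31
#' paths for the low, moderate and high pathways.
#'
#' @param scenario scenario id, one of `names(config$scenarios)`.
#' @param config a [sim_config()].
#' @param cantons subset of cantons to generate (default all).
#' @return A list of paths; each path is a data.frame with columns `date`,
#'   `canton`, `tmax_c`.
#' @export
gen_climate_ensemble <- function(scenario, config, cantons = config$cantons) {
  stopifnot(inherits(config, "sim_config"))
  sc <- config$scenarios[[scenario]]
  if (is.null(sc)) stop("unknown scenario: ", scenario)
  yrs <- config$projection_years
  dates <- year_dates(yrs)
  yr <- as.integer(format(dates, "%Y"))
  ramp_frac <- pmin(1, pmax(0, (yr - min(yrs)) / (2070 - min(yrs))))
  lapply(seq_len(sc$n_sim), function(i) {
    offset <- with_seed(derive_seed(config$seed,
                                    paste0("pathoffset:", scenario, ":", i)),
                        stats::rnorm(1, 0, 0.3))
    do.call(rbind, lapply(cantons, function(cn) {
      p <- config$temperature_params[[cn]]
      tmax <- sinusoid_ar1(
        dates, p$mean, p$amplitude, p$sd, p$ar,
        seed = derive_seed(config$seed,
                           paste0("path:", scenario, ":", i, ":", cn)),
        trend = sc$ramp * ramp_frac + offset)
      data.frame(date = dates, canton = cn, tmax_c = tmax,
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Generate age-specific population growth factors
#'
#' National growth factors by age group and year, anchored at 1 in the
#' reference-period midpoint year and compounding the scenario's annual rates;
#' applied uniformly across cantons. The configured rates reproduce the
#' qualitative demographic pathways: steady growth of the 75+ group under
#' every scenario, stability or slight decline of the younger groups under
#' the low and moderate pathways, and growth of all groups under the high one.
#'
#' @param scenario scenario id.
#' @param config a [sim_config()].
#' @param ref_year anchor year at which every factor equals 1 (midpoint year
#'   of the 2013-2022 reference decade).
#' @return A data.frame with columns `year`, `age_group`, `growth`.
#' @export
gen_demographics <- function(scenario, config, ref_year = 2018) {
  stopifnot(inherits(config, "sim_config"))
  rates <- config$growth_rates[[scenario]]
  if (is.null(rates)) stop("unknown scenario: ", scenario)
  years <- min(config$years):max(config$projection_years)
  out <- do.call(rbind, lapply(names(rates), function(ag) {
    data.frame(year = years, age_group = ag,
               growth = (1 + rates[[ag]])^(years - ref_year),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
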