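# Pipeline orchestration: configuration, delimited-table I/O, run manifests
# and the subcommand runners (simulate / fit / pool / attribute / project /
# report) that wire the stages together on disk artifacts.

#' Default pipeline configuration
#'
#' Returns the full configuration list with the study defaults: six cantons,
#' 1998-2022 history, reference decade 2013-2022, heat threshold computed
#' from the pooled warm-season median (23.3 degrees C in the emulated
#' sample), extreme/moderate report temperatures 34.2 / 29.7 degrees C, 500
#' Monte Carlo draws, three emissions scenarios and projection decades up to
#' the 2060s. Override any element before passing the list to the step
#' runners; [validate_config()] checks the result.
#'
#' @param seed master seed.
#' @export
default_config <- function(seed = 20220101) {
  list(
    seed = seed,
    cantons = c("BE", "BS", "GE", "TI", "VD", "ZH"),
    years = c(1998, 2022),
    ref_years = c(2013, 2022),
    threshold = NULL,                 # NULL: pooled warm-season median
    report_temps = c(extreme = 34.2, moderate = 29.7),
    n_draws = 500,
    year_dummies = TRUE,
    significance_filter = FALSE,
    canton_median_reference = FALSE,  # sensitivity: per-canton thresholds
    min_obs = 100,
    diseases = list(
      endocrine_metabolic = list(slope = 0.030, baseline = 3, dispersion = 1.3),
      urinary             = list(slope = 0.012, baseline = 8, dispersion = 1.4),
      infectious          = list(slope = 0.009, baseline = 10, dispersion = 1.4),
      circulatory         = list(slope = -0.002, baseline = 20, dispersion = 1.5)),
    age_multipliers = c("0-14" = 0.25, "15-74" = 1, "75+" = 0.6),
    scenarios = list(low = list(ramp = 0.0, n_sim = 12),
                     moderate = list(ramp = 1.2, n_sim = 25),
                     high = list(ramp = 2.6, n_sim = 31)),
    growth_rates = list(
      low      = c("0-14" = -0.004, "15-74" = -0.001, "75+" = 0.020),
      moderate = c("0-14" =  0.002, "15-74" =  0.001, "75+" = 0.022),
      high     = c("0-14" =  0.012, "15-74" =  0.010, "75+" = 0.028)),
    projection_years = c(2023, 2074),
    decades = list(c(2030, 2039), c(2040, 2049), c(2050, 2059), c(2060, 2069))
  )
}

#' Validate a pipeline configuration
#'
#' Schema check with field-level messages; returns the config invisibly.
#' @param config configuration list.
#' @export
validate_config <- function(config) {
  fail <- function(field, why) stop("config$", field, ": ", why, call. = FALSE)
  need <- c("seed", "cantons", "years", "ref_years", "n_draws", "diseases",
            "age_multipliers", "scenarios", "growth_rates",
            "projection_years", "decades", "min_obs")
  for (f in need) if (is.null(config[[f]])) fail(f, "missing")
  if (length(config$cantons) < 1) fail("cantons", "need at least one canton")
  if (diff(config$years) < 1) fail("years", "must span >= 2 calendar years")
  if (!is.null(config$threshold) &&
      (config$threshold <= -20 || config$threshold >= 50))
    fail("threshold", "outside plausible range (-20, 50) degrees C")
  if (config$n_draws < 1) fail("n_draws", "must be >= 1")
  for (d in names(config$diseases)) {
    dd <- config$diseases[[d]]
    if (is.null(dd$slope) || is.null(dd$baseline) || is.null(dd$dispersion))
      fail(paste0("diseases$", d), "needs slope, baseline, dispersion")
    if (dd$dispersion < 1) fail(paste0("diseases$", d), "dispersion must be >= 1")
  }
  invisible(config)
}

#' Read / write a pipeline configuration file (YAML)
#' @param path file path.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (nm in c("age_multipliers"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  cfg$growth_rates <- lapply(cfg$growth_rates, unlist)
  validate_config(cfg)
  cfg
}

#' @rdname read_pipeline_config
#' @param config configuration list.
#' @export
write_pipeline_config <- function(config, path) {
  writeLines(config_yaml(config), path)
  invisible(path)
}

# canonical YAML form: named vectors become maps so names survive the trip
config_yaml <- function(config) {
  config$age_multipliers <- as.list(config$age_multipliers)
  config$growth_rates <- lapply(config$growth_rates, as.list)
  yaml::as.yaml(config)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(config_yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a daily table with row-level validation
#'
#' Delimited UTF-8 with a header row and ISO-8601 dates. Rows with malformed
#' dates or negative counts are rejected individually (reported via a
#' warning naming the row numbers); remaining rows are loaded. Unknown
#' columns are preserved.
#'
#' @param path CSV file path.
#' @return data.frame with `date` parsed to `Date`.
#' @export
read_daily_table <- function(path) {
  if (!file.exists(path)) stop("missing input table: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) { d$date <- as.Date(character()); return(d) }
  if ("date" %in% names(d)) {
    parsed <- as.Date(d$date, format = "%Y-%m-%d")
    bad <- is.na(parsed) & !is.na(d$date)
    if ("count" %in% names(d)) bad <- bad | (!is.na(d$count) & d$count < 0)
    if (any(bad)) {
      warning("rejected ", sum(bad), " malformed row(s) in ", basename(path),
              ": rows ", paste(utils::head(which(bad), 10), collapse = ", "))
      d <- d[!bad, , drop = FALSE]
      parsed <- parsed[!bad]
    }
    d$date <- parsed
  }
  rownames(d) <- NULL
  d
}

#' Write a result table (CSV, ISO-8601 dates)
#' @param d data.frame.
#' @param path output path.
#' @export
write_results <- function(d, path) {
  if ("date" %in% names(d)) d$date <- format(d$date, "%Y-%m-%d")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(outdir, step, config, files) {
  man <- list(step = step, config_hash = config_hash(config),
              seed = config$seed, created = format(Sys.time(), "%FT%T%z"),
              files = as.list(files))
  yaml::write_yaml(man, file.path(outdir, paste0("manifest_", step, ".yaml")))
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    stop("missing upstream artifact ", path,
         "; run the '", produced_by, "' step first")
  path
}

sim_config_of <- function(config) {
  sim_config(cantons = config$cantons,
             years = config$years[1]:config$years[2],
             seed = config$seed,
             scenarios = config$scenarios,
             growth_rates = config$growth_rates,
             projection_years = config$projection_years[1]:config$projection_years[2])
}

age_groups_of <- function(config) names(config$age_multipliers)

#' Run one pipeline step
#'
#' Subcommands: `simulate` (generate temperatures, admissions and cost
#' tables), `fit` (first-stage curves per stratum), `pool` (meta-regression
#' and BLUPs per disease group), `attribute` (reference-period attribution),
#' `project` (scenario projections incl. climate-only), `report` (summary
#' tables). Each step reads the previous step's artifacts from `outdir`,
#' writes its own, and records a manifest with the config hash and seed.
#'
#' @param name step name.
#' @param config configuration list (see [default_config()]).
#' @param outdir artifact directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
run_subcommand <- function(name, config, outdir) {
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fn <- switch(name,
               simulate = pipeline_simulate, fit = pipeline_fit,
               pool = pipeline_pool, attribute = pipeline_attribute,
               project = pipeline_project, report = pipeline_report,
               stop("unknown subcommand: ", name))
  files <- fn(config, outdir)
  write_manifest(outdir, name, config, files)
  invisible(files)
}

pipeline_simulate <- function(config, outdir) {
  sc <- sim_config_of(config)
  temps <- do.call(rbind, lapply(config$cantons,
                                 function(cn) gen_temperature(sc, cn)))
  ref_temp <- if (is.null(config$threshold))
    warm_season_threshold(temps) else config$threshold
  ages <- age_groups_of(config)
  adm <- list()
  for (cn in config$cantons) {
    tc <- temps[temps$canton == cn, ]
    for (dg in names(config$diseases)) {
      dd <- config$diseases[[dg]]
      for (ag in ages) {
        truth <- true_surface(ref_temp = ref_temp, log_rr_slope = dd$slope,
                              baseline_rate = dd$baseline *
                                config$age_multipliers[[ag]],
                              dispersion = dd$dispersion)
        cnt <- gen_admissions(tc, truth,
                              seed = derive_seed(config$seed,
                                                 paste("adm", cn, dg, ag)))
        cnt$canton <- cn; cnt$disease_group <- dg; cnt$age_group <- ag
        adm[[length(adm) + 1L]] <- cnt
      }
    }
  }
  adm <- do.call(rbind, adm)
  costs <- gen_cost_tables(sc, disease_groups = names(config$diseases),
                           age_groups = ages)
  files <- file.path(outdir, c("temperatures.csv", "admissions.csv",
                               "cost_weights.csv", "base_rates.csv"))
  write_results(temps, files[1])
  write_results(adm, files[2])
  write_results(costs$cost_weight, files[3])
  write_results(costs$base_rate, files[4])
  message("simulate: ", length(config$cantons), " cantons, ",
          length(config$diseases), " disease groups, ", length(ages),
          " age groups")
  files
}

curves_to_df <- function(curves) {
  do.call(rbind, lapply(curves, function(cu) {
    k <- length(cu$coef)
    row <- data.frame(canton = cu$canton, disease_group = cu$disease_group,
                      age_group = cu$age_group, hist_max = cu$hist_max,
                      ref_temp = cu$spec$ref_temp,
                      knot1 = cu$spec$exposure_knots[1],
                      knot2 = cu$spec$exposure_knots[2],
                      knot3 = cu$spec$exposure_knots[3],
                      stringsAsFactors = FALSE)
    for (j in seq_len(k)) row[[paste0("coef", j)]] <- cu$coef[j]
    for (a in seq_len(k)) for (b in seq_len(k))
      row[[paste0("v", a, "_", b)]] <- cu$vcov[a, b]
    row
  }))
}

df_to_curves <- function(d) {
  lapply(seq_len(nrow(d)), function(i) {
    r <- d[i, ]
    k <- length(grep("^coef", names(d)))
    V <- matrix(NA_real_, k, k)
    for (a in seq_len(k)) for (b in seq_len(k))
      V[a, b] <- r[[paste0("v", a, "_", b)]]
    spec <- basis_spec(c(r$knot1, r$knot2, r$knot3), ref_temp = r$ref_temp)
    reduced_curve(coef = unlist(r[paste0("coef", seq_len(k))]),
                  vcov = nearest_psd(V), spec = spec, hist_max = r$hist_max,
                  canton = r$canton, disease_group = r$disease_group,
                  age_group = r$age_group)
  })
}

pipeline_fit <- function(config, outdir) {
  temps <- read_daily_table(require_artifact(
    file.path(outdir, "temperatures.csv"), "simulate"))
  adm <- read_daily_table(require_artifact(
    file.path(outdir, "admissions.csv"), "simulate"))
  ref_temp <- if (is.null(config$threshold))
    warm_season_threshold(temps) else config$threshold
  spec <- basis_spec_from_data(temps, ref_temp = ref_temp)
  tot <- stats::aggregate(count ~ canton + disease_group + age_group, adm, sum)
  names(tot)[names(tot) == "count"] <- "total"
  tot <- stratum_inclusion(tot, min_obs = config$min_obs)
  n_excl <- sum(!tot$include)
  if (n_excl > 0)
    message("fit: excluding ", n_excl, " stratum/strata below ",
            config$min_obs, " observations")
  curves <- list()
  for (i in which(tot$include)) {
    cn <- tot$canton[i]; dg <- tot$disease_group[i]; ag <- tot$age_group[i]
    ser <- stratum_series(temps[temps$canton == cn, ],
                          adm[adm$canton == cn & adm$disease_group == dg &
                                adm$age_group == ag, ],
                          canton = cn, disease_group = dg, age_group = ag)
    fit <- fit_stratum(ser, spec, year_dummies = config$year_dummies)
    curves[[length(curves) + 1L]] <- reduce_cumulative(fit)
  }
  message("fit: ", length(curves), " strata fitted")
  files <- file.path(outdir, "curves.csv")
  write_results(curves_to_df(curves), files)
  files
}

canton_predictors <- function(temps, adm) {
  meds <- vapply(split(temps, temps$canton), function(d)
    stats::median(d$tmax_c[is_warm_season(d$date)]), numeric(1))
  tots <- vapply(split(adm, adm$canton), function(d) sum(d$count), numeric(1))
  data.frame(canton = names(meds), med_warm_temp = as.numeric(meds),
             total_count = as.numeric(tots[names(meds)]),
             stringsAsFactors = FALSE)
}

pipeline_pool <- function(config, outdir) {
  d <- read_daily_table(require_artifact(file.path(outdir, "curves.csv"),
                                         "fit"))
  temps <- read_daily_table(file.path(outdir, "temperatures.csv"))
  adm <- read_daily_table(file.path(outdir, "admissions.csv"))
  pred <- canton_predictors(temps, adm)
  blups <- list()
  for (dg in unique(d$disease_group)) {
    curves <- df_to_curves(d[d$disease_group == dg, ])
    md <- meta_dataset(curves, pred)
    fit <- fit_meta(md)
    message("pool: ", dg, " pooled over ", nrow(md$theta), " strata")
    blups <- c(blups, compute_blups(fit))
  }
  files <- file.path(outdir, "blups.csv")
  write_results(curves_to_df(blups), files)
  files
}

pipeline_attribute <- function(config, outdir) {
  blups <- df_to_curves(read_daily_table(require_artifact(
    file.path(outdir, "blups.csv"), "pool")))
  temps <- read_daily_table(file.path(outdir, "temperatures.csv"))
  adm <- read_daily_table(file.path(outdir, "admissions.csv"))
  costs <- cost_table(
    read_daily_table(file.path(outdir, "cost_weights.csv")),
    read_daily_table(file.path(outdir, "base_rates.csv")))
  threshold <- if (is.null(config$threshold))
    warm_season_threshold(temps) else config$threshold
  ref_years <- config$ref_years[1]:config$ref_years[2]
  cost_year <- max(config$years)
  recs <- do.call(rbind, lapply(blups, function(cu) {
    uc <- stratum_cost(costs, cost_year, cu$disease_group, cu$age_group,
                       cu$canton)
    dr <- sample_coefficients(cu, n = config$n_draws,
                              seed = derive_seed(config$seed,
                                                 paste("mc", cu$canton,
                                                       cu$disease_group,
                                                       cu$age_group)))
    tc <- temps[temps$canton == cu$canton, ]
    # sensitivity variant: per-canton warm-season median as threshold and
    # RR re-centering point
    thr_c <- if (isTRUE(config$canton_median_reference))
      warm_season_threshold(tc) else threshold
    attribute_period(cu, tc,
                     adm[adm$canton == cu$canton &
                           adm$disease_group == cu$disease_group &
                           adm$age_group == cu$age_group, ],
                     unit_cost = uc, years = ref_years,
                     threshold = thr_c, draws = dr,
                     recenter_temp = if (isTRUE(config$canton_median_reference))
                       thr_c else NULL)
  }))
  if (isTRUE(config$significance_filter)) recs <- filter_significant(recs)
  files <- file.path(outdir, "attribution.csv")
  write_results(recs, files)
  message("attribute: ", nrow(recs), " stratum records; total annual cost CHF ",
          format(round(sum(recs$cost))))
  files
}

pipeline_project <- function(config, outdir) {
  blups <- df_to_curves(read_daily_table(require_artifact(
    file.path(outdir, "blups.csv"), "pool")))
  attr_rec <- read_daily_table(require_artifact(
    file.path(outdir, "attribution.csv"), "attribute"))
  temps <- read_daily_table(file.path(outdir, "temperatures.csv"))
  adm <- read_daily_table(file.path(outdir, "admissions.csv"))
  threshold <- if (is.null(config$threshold))
    warm_season_threshold(temps) else config$threshold
  ref_years <- config$ref_years[1]:config$ref_years[2]
  sc <- sim_config_of(config)
  recs <- list()
  for (scen in names(config$scenarios)) {
    ens <- gen_climate_ensemble(scen, sc)
    demo <- gen_demographics(scen, sc)
    for (cu in blups) {
      tc <- temps[temps$canton == cu$canton, ]
      cnt <- adm[adm$canton == cu$canton &
                   adm$disease_group == cu$disease_group &
                   adm$age_group == cu$age_group, ]
      h_ref <- reference_h(tc, cnt, ref_years, threshold)
      ref_rec <- attr_rec[attr_rec$canton == cu$canton &
                            attr_rec$disease_group == cu$disease_group &
                            attr_rec$age_group == cu$age_group, ]
      if (nrow(ref_rec) == 0L) next   # filtered out upstream
      ens_cn <- lapply(ens, function(p) p[p$canton == cu$canton, ])
      for (dec in config$decades) {
        decade <- dec[1]:dec[2]
        g <- demo$growth[demo$age_group == cu$age_group &
                           demo$year %in% decade]
        if (length(g) == 0L)
          stop("no growth factors for age group ", cu$age_group,
               " in decade ", dec[1], "-", dec[2])
        for (variant in c("full", "climate_only")) {
          rec <- project_stratum(cu, ens_cn, tc, h_ref,
                                 growth = if (variant == "full") mean(g) else 1,
                                 unit_cost = ref_rec$unit_cost[1],
                                 decade = decade, ref_years = ref_years,
                                 threshold = threshold, scenario = scen,
                                 ref_record = ref_rec)
          rec$variant <- variant
          recs[[length(recs) + 1L]] <- rec
        }
      }
    }
    message("project: scenario ", scen, " done (", length(ens), " paths)")
  }
  files <- file.path(outdir, "projection.csv")
  write_results(do.call(rbind, recs), files)
  files
}

pipeline_report <- function(config, outdir) {
  attr_rec <- read_daily_table(require_artifact(
    file.path(outdir, "attribution.csv"), "attribute"))
  proj <- read_daily_table(require_artifact(
    file.path(outdir, "projection.csv"), "project"))
  by_canton <- stats::aggregate(cost ~ canton, attr_rec, sum)
  by_canton <- rbind(by_canton,
                     data.frame(canton = "Total",
                                cost = sum(by_canton$cost)))
  summ <- decadal_summary(proj[proj$variant == "full", ],
                          by = c("scenario", "decade", "age_group"))
  files <- file.path(outdir, c("report_costs_by_canton.csv",
                               "report_decadal_summary.csv"))
  write_results(by_canton, files[1])
  write_results(summ, files[2])
  files
}
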