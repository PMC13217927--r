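# Scenario engine: project heat-attributable admissions and costs over
# 2023-2074 per emissions pathway, with the climate-only counterfactual and
# decadal change summaries. Vulnerability (the exposure-response curves) is
# held at its historical estimate throughout.

#' Frequency ratio of exposure days
#'
#' Mean annual number of days above the heat threshold (all seasons) in a
#' projected window divided by the mean annual number in the historical
#' reference window.
#'
#' @param path data.frame `date`, `tmax_c`: one projected climate path for
#'   one canton.
#' @param ref_temps data.frame `date`, `tmax_c`: historical series for the
#'   same canton.
#' @param decade integer years of the projection window.
#' @param ref_years integer years of the reference window (default
#'   2013:2022).
#' @param threshold heat threshold, degrees C.
#' @export
freq_ratio <- function(path, ref_temps, decade, ref_years = 2013:2022,
                       threshold = 23.3) {
  ann_days <- function(d, yrs) {
    y <- as.integer(format(d$date, "%Y"))
    d <- d[y %in% yrs, , drop = FALSE]
    if (nrow(d) == 0L) stop("empty window in frequency ratio")
    nrow(heat_days(d, threshold)) / length(unique(format(d$date, "%Y")))
  }
  ref <- ann_days(ref_temps, ref_years)
  if (ref == 0) stop("zero reference exposure days: frequency ratio undefined")
  ann_days(path, decade) / ref
}

# Mean annual exposure-day admissions of a stratum over the reference decade.
reference_h <- function(temps, counts, ref_years = 2013:2022,
                        threshold = 23.3) {
  d <- merge(temps[c("date", "tmax_c")], counts[c("date", "count")],
             by = "date")
  d$year <- as.integer(format(d$date, "%Y"))
  d <- d[d$year %in% ref_years, ]
  hd <- heat_days(d, threshold)
  sum(hd$count) / length(ref_years)
}

#' Project one stratum under one climate path
#'
#' The projected attributable number factorises as
#' `AN = AF x h_ref x growth x freq`: the attributable fraction from the
#' average RR over the path's exposure days in the decade (extrapolated
#' curve), the reference-period mean annual exposure-day admissions, the
#' age-specific population growth factor, and the exposure-day frequency
#' ratio. Costs use the fixed reference-year unit cost.
#'
#' @param curve the stratum's BLUP curve.
#' @param path projected climate path for the stratum's canton (`date`,
#'   `tmax_c`).
#' @param ref_temps historical temperatures for the canton.
#' @param h_ref reference mean annual exposure-day admissions (see
#'   [reference_h()]).
#' @param growth scalar age-specific growth factor for the decade (mean of
#'   the annual factors over the decade's years), or 1 for the climate-only
#'   counterfactual.
#' @param unit_cost CHF per admission at reference-year tariffs.
#' @param decade projection window years, e.g. `2060:2069`.
#' @param ref_years reference window years.
#' @param threshold heat threshold, degrees C.
#' @param coef optional replacement coefficients (Monte Carlo draws).
#' @return A one-row data.frame with `rr`, `af`, `h_ref`, `growth`, `freq`,
#'   `an`, `cost`.
#' @export
project_stratum_path <- function(curve, path, ref_temps, h_ref, growth,
                                 unit_cost, decade, ref_years = 2013:2022,
                                 threshold = 23.3, coef = curve$coef) {
  y <- as.integer(format(path$date, "%Y"))
  win <- path[y %in% decade, , drop = FALSE]
  hd <- heat_days(win, threshold)
  if (nrow(hd) == 0L) stop("no projected exposure days in window")
  rr <- average_rr(curve, hd$tmax_c, coef = coef)
  af <- attributable_fraction(rr)
  fr <- freq_ratio(path, ref_temps, decade, ref_years, threshold)
  an <- af * h_ref * growth * fr
  data.frame(rr = rr, af = af, h_ref = h_ref, growth = growth, freq = fr,
             an = an, cost = an * unit_cost)
}

#' Project one stratum under a scenario ensemble
#'
#' Runs [project_stratum_path()] for every path of the scenario's climate
#' ensemble and aggregates: point estimates are means across paths; when a
#' draw set is supplied, Monte Carlo draws are pooled across paths so the
#' empirical interval reflects both coefficient uncertainty and inter-model
#' spread.
#'
#' @param curve stratum BLUP curve.
#' @param ensemble list of climate paths for the stratum's canton (each
#'   `date`, `tmax_c`).
#' @param ref_temps,h_ref,growth,unit_cost,decade,ref_years,threshold as in
#'   [project_stratum_path()].
#' @param scenario scenario label stored on the record.
#' @param ref_record optional reference [attribute_period()] record; adds
#'   `pct_change` (percent change of cost vs the reference cost).
#' @param draws optional [sample_coefficients()] draw set.
#' @return A one-row data.frame (class `projection_record`).
#' @export
project_stratum <- function(curve, ensemble, ref_temps, h_ref, growth,
                            unit_cost, decade, ref_years = 2013:2022,
                            threshold = 23.3, scenario = NA_character_,
                            ref_record = NULL, draws = NULL) {
  per_path <- lapply(ensemble, function(p)
    project_stratum_path(curve, p, ref_temps, h_ref, growth, unit_cost,
                         decade, ref_years, threshold))
  pp <- do.call(rbind, per_path)
  # scenario-level quantities: AF and freq are ensemble means, and the
  # attributable number is their exact product (per the projection identity),
  # not the mean of per-path products
  af <- mean(pp$af); fr <- mean(pp$freq)
  an <- af * h_ref * growth * fr
  rec <- data.frame(canton = curve$canton,
                    disease_group = curve$disease_group,
                    age_group = curve$age_group, scenario = scenario,
                    decade = paste(range(decade), collapse = "-"),
                    rr = mean(pp$rr), af = af, h_ref = h_ref,
                    growth = growth, freq = fr,
                    an = an, cost = an * unit_cost,
                    stringsAsFactors = FALSE)
  if (!is.null(draws)) {
    hd_by_path <- lapply(ensemble, function(p) {
      y <- as.integer(format(p$date, "%Y"))
      heat_days(p[y %in% decade, , drop = FALSE], threshold)$tmax_c
    })
    sims <- t(apply(draws$draws, 1, function(cf) {
      afs <- vapply(hd_by_path, function(td)
        attributable_fraction(average_rr(curve, td, coef = cf)), numeric(1))
      rrs <- vapply(hd_by_path, function(td)
        average_rr(curve, td, coef = cf), numeric(1))
      an_d <- mean(afs) * h_ref * growth * fr
      c(rr = mean(rrs), an = an_d, cost = an_d * unit_cost)
    }))
    q <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
    for (nm in c("rr", "an", "cost")) {
      qs <- q(sims[, nm])
      rec[[paste0(nm, "_lo")]] <- qs[1]
      rec[[paste0(nm, "_hi")]] <- qs[2]
    }
  }
  if (!is.null(ref_record)) {
    rec$cost_ref <- ref_record$cost
    rec$pct_change <- if (ref_record$cost == 0) NA_real_ else
      100 * (rec$cost - ref_record$cost) / abs(ref_record$cost)
  }
  class(rec) <- c("projection_record", class(rec))
  rec
}

#' Climate-only counterfactual projection
#'
#' Identical to [project_stratum()] with the population growth factor forced
#' to 1, isolating the warming contribution to the projected change.
#' @inheritParams project_stratum
#' @export
climate_only <- function(curve, ensemble, ref_temps, h_ref, unit_cost,
                         decade, ref_years = 2013:2022, threshold = 23.3,
                         scenario = NA_character_, ref_record = NULL,
                         draws = NULL) {
  project_stratum(curve, ensemble, ref_temps, h_ref, growth = 1,
                  unit_cost = unit_cost, decade = decade,
                  ref_years = ref_years, threshold = threshold,
                  scenario = scenario, ref_record = ref_record, draws = draws)
}

#' Share of a projected cost increase attributable to climate alone
#'
#' Ratio of the climate-only cost increase to the full-scenario cost
#' increase over the same reference; undefined (NA with a flag) when the
#' full-scenario increase is near zero.
#' @param full,climate projection records for the same stratum/decade.
#' @param ref reference attribution record.
#' @export
climate_share <- function(full, climate, ref) {
  d_full <- full$cost - ref$cost
  d_clim <- climate$cost - ref$cost
  if (abs(d_full) < 1e-9 * max(1, abs(ref$cost))) return(NA_real_)
  d_clim / d_full
}

#' Decadal change summary across strata
#'
#' Aggregates projection records by scenario x age group (and optionally
#' canton): costs and attributable numbers are summed across strata within
#' each cell, RR is averaged across cantons, and the percent change is taken
#' against the summed reference costs.
#'
#' @param records data.frame of projection records (rows from
#'   [project_stratum()]), carrying `cost_ref`.
#' @param by grouping columns (default scenario, age group).
#' @return data.frame with summed `cost`, summed `cost_ref`, mean `rr` and
#'   `pct_change` per group.
#' @export
decadal_summary <- function(records, by = c("scenario", "age_group")) {
  stopifnot(all(c(by, "cost", "cost_ref", "rr") %in% names(records)))
  agg <- stats::aggregate(records[c("cost", "cost_ref", "an")],
                          records[by], sum)
  rr <- stats::aggregate(records["rr"], records[by], mean)
  out <- merge(agg, rr, by = by)
  out$pct_change <- 100 * (out$cost - out$cost_ref) / abs(out$cost_ref)
  out
}
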