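# Heat relative risks, attributable fractions, attributable numbers and
# heat-attributable costs for the historical reference period, with
# sensitivity variants.

# Linear functional c(t) such that cumulative log-RR(t) = c(t)' theta,
# including the extrapolation rule: beyond the stratum's historical maximum
# the curve continues with the spline's end slope for 5 degrees C, then is
# constant. Returns a length(t) x k matrix.
logrr_contrast <- function(curve, t) {
  hm <- curve$hist_max
  tcap <- pmin(t, hm)
  Bc <- centered_exposure_basis(tcap, curve$spec)
  over <- t > hm
  if (any(over)) {
    h <- 1e-4
    dB <- (exposure_basis(hm + h / 2, curve$spec) -
             exposure_basis(hm - h / 2, curve$spec)) / h
    extra <- pmin(t[over], hm + 5) - hm
    Bc[over, ] <- Bc[over, , drop = FALSE] + extra %o% as.numeric(dB)
  }
  Bc
}

#' Cumulative log relative risk of a curve at given temperatures
#'
#' Applies the extrapolation rule beyond the historical maximum (log-linear
#' continuation with the end slope for 5 degrees C, then constant risk).
#' @param curve a [reduced_curve()] or BLUP curve.
#' @param t temperature(s), degrees C.
#' @param coef optional replacement coefficient vector (used for Monte Carlo
#'   draws).
#' @export
cum_logrr <- function(curve, t, coef = curve$coef) {
  as.numeric(logrr_contrast(curve, t) %*% coef)
}

#' Relative risk at given temperatures, with confidence interval
#'
#' RR(t) = exp(theta . (B(t) - B(t_ref))) with the extrapolation rule of
#' [cum_logrr()]; the interval comes from the curve covariance by the delta
#' method on the log scale, or from Monte Carlo draws if supplied.
#'
#' @param curve a curve object.
#' @param t temperature(s), degrees C.
#' @param level confidence level.
#' @param draws optional [sample_coefficients()] draw set for percentile
#'   intervals.
#' @return data.frame with columns `t`, `rr`, `rr_lo`, `rr_hi`.
#' @export
rr_at <- function(curve, t, level = 0.95, draws = NULL) {
  Cmat <- logrr_contrast(curve, t)
  lr <- as.numeric(Cmat %*% curve$coef)
  if (is.null(draws)) {
    se <- sqrt(pmax(0, rowSums((Cmat %*% curve$vcov) * Cmat)))
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- exp(lr - z * se); hi <- exp(lr + z * se)
  } else {
    sims <- exp(draws$draws %*% t(Cmat))
    qs <- apply(sims, 2, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    lo <- qs[1, ]; hi <- qs[2, ]
  }
  data.frame(t = t, rr = exp(lr), rr_lo = lo, rr_hi = hi)
}

#' Warm-season median temperature threshold
#'
#' The heat threshold: median daily maximum temperature over May-September
#' days of the supplied (pooled) historical series.
#' @param temps data.frame with `date`, `tmax_c`.
#' @export
warm_season_threshold <- function(temps) {
  stats::median(temps$tmax_c[is_warm_season(temps$date)])
}

#' Identify heat-exposed days
#'
#' Days whose maximum temperature strictly exceeds the threshold. Historical
#' thresholds derive from warm-season days only ([warm_season_threshold()]);
#' the day scan itself considers every supplied day regardless of season, as
#' projections must.
#'
#' @param temps data.frame with `date`, `tmax_c`.
#' @param threshold degrees C (default 23.3, the pooled warm-season median of
#'   the study sample).
#' @return The subset of rows of `temps` on heat days.
#' @export
heat_days <- function(temps, threshold = 23.3) {
  temps[temps$tmax_c > threshold, , drop = FALSE]
}

#' Average relative risk over exposure days
#'
#' Arithmetic mean of RR at each exposure day's temperature.
#' @param curve a curve object.
#' @param t temperatures on exposure days.
#' @param coef optional replacement coefficients.
#' @export
average_rr <- function(curve, t, coef = curve$coef) {
  if (length(t) == 0L) stop("no exposure days: average RR undefined")
  mean(exp(cum_logrr(curve, t, coef = coef)))
}

#' Attributable fraction from a relative risk
#'
#' AF = (RR - 1)/RR: the share of exposure-day admissions attributable to
#' heat; zero at RR = 1, negative for protective associations, bounded above
#' by 1.
#' @param rr relative risk(s), > 0.
#' @export
attributable_fraction <- function(rr) {
  if (any(rr <= 0)) stop("relative risk must be > 0")
  (rr - 1) / rr
}

#' Heat attribution for one stratum over a reference period
#'
#' Per calendar year: exposure days are days above the threshold, `a` is the
#' recorded admissions on those days, the average RR over those days gives
#' AF = (RR-1)/RR, the attributable number AN = a x AF, and the
#' heat-attributable cost AN x unit cost (unit cost fixed at the final-year
#' tariff). Annual values are aggregated as the mean over the period.
#'
#' @param curve the stratum's (BLUP) cumulative exposure-response curve.
#' @param temps data.frame `date`, `tmax_c` for the stratum's canton.
#' @param counts data.frame `date`, `count` for the stratum.
#' @param unit_cost CHF per admission for this stratum.
#' @param years reference period (default 2013:2022).
#' @param threshold heat threshold, degrees C.
#' @param draws optional draw set; adds empirical 95% interval columns for
#'   RR, AF, AN and cost.
#' @param recenter_temp optional temperature at which to re-center the RR
#'   (canton-specific median sensitivity variant): risks are expressed
#'   relative to `RR(recenter_temp)` instead of the shared reference.
#' @return A one-row data.frame (class `attribution_record`) with columns
#'   `canton`, `disease_group`, `age_group`, `period`, `rr`, `af`, `a`,
#'   `an`, `unit_cost`, `cost` (+ `_lo`/`_hi` columns when draws given).
#' @export
attribute_period <- function(curve, temps, counts, unit_cost,
                             years = 2013:2022, threshold = 23.3,
                             draws = NULL, recenter_temp = NULL) {
  d <- merge(temps[c("date", "tmax_c")], counts[c("date", "count")],
             by = "date")
  d$year <- as.integer(format(d$date, "%Y"))
  d <- d[d$year %in% years, ]
  if (nrow(d) == 0L) stop("no data in the requested period")
  per_year <- function(coef) {
    rr_ref <- if (is.null(recenter_temp)) 1 else
      exp(cum_logrr(curve, recenter_temp, coef = coef))
    t(vapply(split(d, d$year), function(dy) {
      hd <- hd_of(dy)
      if (nrow(hd) == 0L) return(c(rr = NA_real_, af = 0, a = 0, an = 0))
      rr <- average_rr(curve, hd$tmax_c, coef = coef) / rr_ref
      af <- attributable_fraction(rr)
      a <- sum(hd$count)
      c(rr = rr, af = af, a = a, an = a * af)
    }, numeric(4)))
  }
  hd_of <- function(dy) dy[dy$tmax_c > threshold, , drop = FALSE]
  yr <- per_year(curve$coef)
  if (all(is.na(yr[, "rr"])))
    stop("no exposure days in period: stratum flagged")
  # period aggregates: mean annual exposure-day admissions and mean annual
  # attributable number; the period AF and RR are defined from these so the
  # record identities AF = AN/a = (RR-1)/RR hold exactly
  summarise <- function(y) {
    a <- mean(y[, "a"]); an <- mean(y[, "an"])
    af <- if (a > 0) an / a else 0
    c(rr = 1 / (1 - af), af = af, a = a, an = an, cost = an * unit_cost)
  }
  pt <- summarise(yr)
  rec <- data.frame(canton = curve$canton, disease_group = curve$disease_group,
                    age_group = curve$age_group,
                    period = paste(range(years), collapse = "-"),
                    rr = pt[["rr"]], af = pt[["af"]], a = pt[["a"]],
                    an = pt[["an"]], unit_cost = unit_cost,
                    cost = pt[["cost"]], stringsAsFactors = FALSE)
  if (!is.null(draws)) {
    sims <- t(apply(draws$draws, 1, function(cf) summarise(per_year(cf))))
    q <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
    for (nm in c("rr", "af", "an", "cost")) {
      qs <- q(sims[, nm])
      rec[[paste0(nm, "_lo")]] <- qs[1]
      rec[[paste0(nm, "_hi")]] <- qs[2]
    }
  }
  class(rec) <- c("attribution_record", class(rec))
  rec
}

#' Drop strata whose average heat RR is not significant
#'
#' Keeps records whose 95% interval for the average RR over exposure days
#' excludes 1. Applied optionally before aggregation; it can only reduce an
#' aggregate's absolute magnitude contribution set, never add to it.
#' @param records data.frame of attribution or projection records carrying
#'   `rr_lo` / `rr_hi` columns.
#' @export
filter_significant <- function(records) {
  stopifnot(all(c("rr_lo", "rr_hi") %in% names(records)))
  records[records$rr_lo > 1 | records$rr_hi < 1, , drop = FALSE]
}

#' Severity-multiplier and base-rate-band sensitivity variants
#'
#' Heat-related admissions tend to be more resource-intensive than the DRG
#' group average (longer stays, more complications), so severity multipliers
#' scale the central cost estimate upward; the band reflects the spread of
#' negotiated base rates across hospitals within a canton.
#'
#' @param cost baseline heat-attributable cost (any unit).
#' @param multipliers severity multipliers (> 0), default 1.1 / 1.2 / 1.3.
#' @param band half-width of the relative base-rate band, default 0.15.
#' @return A list with `severity` (named vector of adjusted costs) and
#'   `band` (lower/upper costs).
#' @export
sensitivity_variants <- function(cost, multipliers = c(1.1, 1.2, 1.3),
                                 band = 0.15) {
  if (any(multipliers <= 0)) stop("multipliers must be > 0")
  sev <- cost * multipliers
  names(sev) <- paste0("x", multipliers)
  list(severity = sev,
       band = c(lower = cost * (1 - band), upper = cost * (1 + band)))
}

#' Round CHF amounts to millions at one decimal
#' @param x CHF amounts.
#' @export
chf_millions <- function(x) round(x / 1e6, 1)
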