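# First-stage distributed lag non-linear model: cross-basis of a centered
# quadratic B-spline in temperature and a natural cubic spline in lag,
# quasi-Poisson fit per stratum, and reduction of the fitted surface to a
# one-dimensional cumulative exposure-response curve.

#' Cross-basis specification
#'
#' Fixes the bases shared by every stratum: a quadratic B-spline in
#' temperature with knots at the minimum, median and maximum of the pooled
#' year-round distribution, and a natural cubic spline over integer lags
#' 0-7 with two internal knots equally spaced on the log(lag + 1) scale
#' (lags 1 and 3). The exposure basis is centered at the reference
#' temperature so the fitted cumulative log relative risk is exactly zero
#' there; the lag basis keeps an intercept column.
#'
#' @param exposure_knots three strictly increasing temperatures (min, median,
#'   max of the pooled distribution); the outer two are the boundary knots.
#' @param ref_temp reference (centering) temperature, inside the knot span.
#' @param degree exposure spline degree.
#' @param lag integer lag window, inclusive.
#' @param lag_knots internal knots of the lag spline.
#' @return An object of class `basis_spec`.
#' @export
basis_spec <- function(exposure_knots, ref_temp,
                       degree = 2, lag = c(0L, 7L),
                       lag_knots = exp(log(diff(lag) + 1) * c(1, 2) / 3) - 1) {
  if (length(exposure_knots) != 3L || any(diff(exposure_knots) <= 0))
    stop("exposure_knots must be three strictly increasing temperatures")
  if (ref_temp < exposure_knots[1] || ref_temp > exposure_knots[3])
    stop("ref_temp must lie within the exposure knot span")
  lag <- as.integer(lag)
  if (lag[1] != 0L || lag[2] <= lag[1]) stop("lag window must be 0:L, L >= 1")
  structure(list(exposure_knots = exposure_knots, ref_temp = ref_temp,
                 degree = degree, lag = lag, lag_knots = lag_knots),
            class = "basis_spec")
}

#' Derive the shared basis specification from pooled temperature data
#'
#' Knots at the minimum, median and maximum of the pooled year-round daily
#' maximum temperature across all cantons; reference temperature defaulting
#' to the pooled warm-season (May-September) median, the climatologically
#' "typical warm day" against which heat excess is measured.
#'
#' @param temps data.frame with columns `date`, `tmax_c` pooled over cantons.
#' @param ref_temp optional override of the reference temperature.
#' @export
basis_spec_from_data <- function(temps, ref_temp = NULL) {
  x <- temps$tmax_c
  if (is.null(ref_temp))
    ref_temp <- stats::median(x[is_warm_season(temps$date)])
  basis_spec(exposure_knots = c(min(x), stats::median(x), max(x)),
             ref_temp = ref_temp)
}

# Uncentered exposure basis; linear continuation beyond the boundary knots
# (value + one-sided slope) so predictions degrade gracefully out of range.
exposure_basis <- function(x, spec) {
  bk <- spec$exposure_knots[c(1, 3)]
  inner <- spec$exposure_knots[2]
  ev <- function(z) splines::bs(z, knots = inner, Boundary.knots = bk,
                                degree = spec$degree)
  xc <- pmin(pmax(x, bk[1]), bk[2])
  B <- unclass(ev(xc))
  out_lo <- x < bk[1]
  out_hi <- x > bk[2]
  if (any(out_lo | out_hi)) {
    h <- diff(bk) * 1e-6
    if (any(out_hi)) {
      d <- (ev(bk[2]) - ev(bk[2] - h)) / h
      B[out_hi, ] <- B[out_hi, , drop = FALSE] +
        (x[out_hi] - bk[2]) %o% as.numeric(d)
    }
    if (any(out_lo)) {
      d <- (ev(bk[1] + h) - ev(bk[1])) / h
      B[out_lo, ] <- B[out_lo, , drop = FALSE] +
        (x[out_lo] - bk[1]) %o% as.numeric(d)
    }
  }
  dimnames(B) <- NULL
  B
}

# Centered exposure basis: B(x) - B(ref), so every column is 0 at ref_temp.
centered_exposure_basis <- function(x, spec) {
  B <- exposure_basis(x, spec)
  Bref <- exposure_basis(spec$ref_temp, spec)
  sweep(B, 2, as.numeric(Bref))
}

# Natural cubic lag basis over integer lags, intercept column included.
lag_basis <- function(spec) {
  l <- spec$lag[1]:spec$lag[2]
  C <- splines::ns(l, knots = spec$lag_knots,
                   Boundary.knots = range(l), intercept = TRUE)
  C <- unclass(C)
  dimnames(C) <- NULL
  C
}

#' Build the cross-basis design matrix
#'
#' Row t, column (j, k) holds `sum_l Bc_j(T[t-l]) * C_k(l)` over the lag
#' window, where `Bc` is the centered exposure basis and `C` the lag basis.
#' The first `L` rows (incomplete lag window) are set to `NA` and are dropped
#' from the likelihood at fitting time.
#'
#' @param tmax numeric vector of daily maximum temperatures in time order.
#' @param spec a [basis_spec()].
#' @return An n x (J*K) matrix with attributes `spec`, `J`, `K`; columns
#'   ordered exposure-dimension-major (`b1.l1, b1.l2, ..., b2.l1, ...`).
#' @export
build_crossbasis <- function(tmax, spec) {
  L <- spec$lag[2]
  n <- length(tmax)
  if (n <= L) stop("series length must exceed the lag window")
  Bc <- centered_exposure_basis(tmax, spec)
  C <- lag_basis(spec)
  J <- ncol(Bc); K <- ncol(C)
  Q <- matrix(0, n, J * K)
  for (l in 0:L) {
    idx <- (l + 1):n
    Ml <- Bc[idx - l, , drop = FALSE]
    for (k in seq_len(K)) {
      cols <- (seq_len(J) - 1L) * K + k
      Q[idx, cols] <- Q[idx, cols] + Ml * C[l + 1, k]
    }
  }
  Q[seq_len(L), ] <- NA_real_
  colnames(Q) <- paste0("b", rep(seq_len(J), each = K),
                        ".l", rep(seq_len(K), J))
  attr(Q, "spec") <- spec
  attr(Q, "J") <- J
  attr(Q, "K") <- K
  Q
}

#' Assemble a stratum series
#'
#' Aligns daily admissions and temperature for one canton x disease x age
#' stratum and attaches the calendar covariates used for confounding control.
#'
#' @param temps data.frame with `date`, `tmax_c`.
#' @param counts data.frame with `date`, `count`.
#' @param canton,disease_group,age_group stratum labels.
#' @param holidays Date vector; defaults to fixed-date national holidays.
#' @return An object of class `stratum_series`: a data.frame with columns
#'   `date`, `tmax_c`, `count`, `dow`, `month`, `year`, `holiday`.
#' @export
stratum_series <- function(temps, counts, canton = NA_character_,
                           disease_group = NA_character_,
                           age_group = NA_character_, holidays = NULL) {
  d <- merge(temps[c("date", "tmax_c")], counts[c("date", "count")],
             by = "date")
  d <- d[order(d$date), ]
  if (nrow(d) == 0L) stop("temps and counts share no dates")
  if (any(diff(as.integer(d$date)) != 1L)) stop("dates must be contiguous")
  if (any(is.na(d$tmax_c))) stop("missing Tmax inside the fitting window")
  if (any(d$count < 0 | d$count != round(d$count)))
    stop("counts must be non-negative integers")
  yrs <- as.integer(format(range(d$date), "%Y"))
  if (is.null(holidays)) holidays <- holiday_dates_default(yrs[1]:yrs[2])
  d$dow <- factor(as.integer(format(d$date, "%u")), levels = 1:7)
  d$month <- factor(as.integer(format(d$date, "%m")), levels = 1:12)
  d$year <- factor(format(d$date, "%Y"))
  d$holiday <- d$date %in% holidays
  rownames(d) <- NULL
  structure(d, class = c("stratum_series", "data.frame"),
            canton = canton, disease_group = disease_group,
            age_group = age_group)
}

#' Fit the first-stage quasi-Poisson DLNM for one stratum
#'
#' `log E[count] = alpha + crossbasis(Tmax) + dow + month + holiday (+ year)`,
#' fitted by iteratively reweighted least squares with a quasi-Poisson
#' variance. The dispersion is the Pearson chi-square over residual degrees
#' of freedom and scales the coefficient covariance. Leading lag-window days
#' are dropped from the likelihood.
#'
#' @param series a [stratum_series()].
#' @param spec a [basis_spec()].
#' @param year_dummies include calendar-year indicator variables for
#'   long-term trend control (default TRUE; disabled automatically for
#'   single-year series).
#' @param epsilon,maxit IRLS convergence tolerance on relative deviance
#'   change and iteration cap.
#' @return An object of class `first_stage_fit` with elements `coef`, `vcov`
#'   (scaled by the dispersion), `dispersion`, `eta_index` (positions of the
#'   cross-basis block), `spec`, `hist_max`, stratum labels and `glm` fit
#'   summary fields.
#' @export
fit_stratum <- function(series, spec, year_dummies = TRUE,
                        epsilon = 1e-8, maxit = 100) {
  stopifnot(inherits(series, "stratum_series"), inherits(spec, "basis_spec"))
  if (all(series$count == 0)) stop("stratum has no nonzero counts")
  cb <- build_crossbasis(series$tmax_c, spec)
  J <- attr(cb, "J"); K <- attr(cb, "K")
  keep <- stats::complete.cases(cb)
  dat <- series[keep, , drop = FALSE]
  cb <- cb[keep, , drop = FALSE]
  dat$dow <- droplevels(dat$dow)
  dat$month <- droplevels(dat$month)
  dat$year <- droplevels(dat$year)
  use_year <- year_dummies && nlevels(dat$year) > 1L
  fml <- stats::as.formula(paste(
    "count ~ cb",
    if (nlevels(dat$dow) > 1L) "+ dow" else "",
    if (nlevels(dat$month) > 1L) "+ month" else "",
    if (any(dat$holiday) && !all(dat$holiday)) "+ holiday" else "",
    if (use_year) "+ year" else ""))
  fit <- stats::glm(fml, data = dat, family = stats::quasipoisson(),
                    control = stats::glm.control(epsilon = epsilon,
                                                 maxit = maxit))
  if (!fit$converged)
    stop("IRLS did not converge in ", maxit,
         " iterations (final deviance ", format(fit$deviance), ")")
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("design is rank deficient; collinear columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)
  phi <- sm$dispersion   # Pearson chi-square / residual df
  V <- phi * sm$cov.unscaled
  eta_index <- grep("^cb", names(cf))
  structure(list(coef = cf, vcov = V, dispersion = phi,
                 eta_index = eta_index, spec = spec,
                 J = J, K = K,
                 hist_max = max(series$tmax_c),
                 n = nrow(dat), df_residual = fit$df.residual,
                 deviance = fit$deviance,
                 canton = attr(series, "canton"),
                 disease_group = attr(series, "disease_group"),
                 age_group = attr(series, "age_group")),
            class = "first_stage_fit")
}

#' Reduce a fitted surface to the cumulative exposure-response curve
#'
#' Sums the lag dimension out of the cross-basis block: with lag-basis column
#' sums `s_k = sum_l C_k(l)`, the reduced coefficient on exposure basis
#' column j is `theta_j = sum_k eta_{jk} s_k`, and the covariance is the same
#' linear map applied to the cross-basis block of the fit covariance. The
#' resulting curve gives the summed-over-lags log relative risk of sustained
#' exposure at each temperature, exactly zero at the reference temperature.
#'
#' @param fit a [first_stage_fit()][fit_stratum].
#' @return An object of class `reduced_curve` with elements `coef` (theta),
#'   `vcov`, `spec`, `hist_max` and the stratum labels.
#' @export
reduce_cumulative <- function(fit) {
  stopifnot(inherits(fit, "first_stage_fit"))
  spec <- fit$spec
  s <- colSums(lag_basis(spec))
  J <- fit$J; K <- fit$K
  M <- matrix(0, J, J * K)
  for (j in seq_len(J)) M[j, (j - 1L) * K + seq_len(K)] <- s
  eta <- fit$coef[fit$eta_index]
  Veta <- fit$vcov[fit$eta_index, fit$eta_index, drop = FALSE]
  reduced_curve(coef = as.numeric(M %*% eta),
                vcov = M %*% Veta %*% t(M),
                spec = spec, hist_max = fit$hist_max,
                canton = fit$canton, disease_group = fit$disease_group,
                age_group = fit$age_group)
}

#' Construct a reduced cumulative exposure-response curve
#'
#' @param coef reduced coefficients on the centered exposure basis.
#' @param vcov their covariance (symmetric PSD).
#' @param spec the shared [basis_spec()].
#' @param hist_max historical maximum temperature of the stratum, the anchor
#'   of the extrapolation rule used by [rr_at()].
#' @param canton,disease_group,age_group stratum labels.
#' @export
reduced_curve <- function(coef, vcov, spec, hist_max,
                          canton = NA_character_,
                          disease_group = NA_character_,
                          age_group = NA_character_) {
  vcov <- (vcov + t(vcov)) / 2
  if (length(coef) != nrow(vcov)) stop("coef/vcov dimension mismatch")
  if (!is_psd(vcov)) stop("curve covariance is not positive semi-definite")
  structure(list(coef = as.numeric(coef), vcov = vcov, spec = spec,
                 hist_max = hist_max, canton = canton,
                 disease_group = disease_group, age_group = age_group),
            class = "reduced_curve")
}

#' @export
print.reduced_curve <- function(x, ...) {
  cat("Cumulative exposure-response curve",
      sprintf("[%s / %s / %s]\n", x$canton, x$disease_group, x$age_group))
  cat("  ref temp:", format(x$spec$ref_temp), "C;  hist max:",
      format(x$hist_max), "C\n")
  cat("  coef:", paste(format(x$coef, digits = 4), collapse = " "), "\n")
  invisible(x)
}

# Cumulative log-RR of a curve at temperatures t, without the extrapolation
# rule (pure basis evaluation; the rule lives in rr_at()).
cum_logrr_basis <- function(curve, t) {
  Bc <- centered_exposure_basis(t, curve$spec)
  as.numeric(Bc %*% curve$coef)
}
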