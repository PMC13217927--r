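# Monte Carlo propagation of coefficient uncertainty: multivariate normal
# draws of curve coefficients and empirical percentile intervals of any
# statistic computed from them.

#' Sample coefficient vectors from a fitted curve
#'
#' Multivariate normal draws around the curve coefficients with the curve
#' covariance. A covariance that fails the positive-semi-definite check is
#' repaired to the nearest PSD matrix with a warning.
#'
#' @param curve a [reduced_curve()] or BLUP curve.
#' @param n number of draws (default 500).
#' @param seed integer seed.
#' @return An object of class `draw_set`: list with `draws` (n x k matrix),
#'   `center`, `seed`.
#' @export
sample_coefficients <- function(curve, n = 500, seed) {
  stopifnot(inherits(curve, "reduced_curve"), n >= 1)
  V <- curve$vcov
  if (!is_psd(V)) {
    warning("curve covariance not PSD; repairing to nearest PSD matrix")
    V <- nearest_psd(V)
  }
  k <- length(curve$coef)
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  R <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), k)
  Z <- with_seed(seed, matrix(stats::rnorm(n * k), n, k))
  draws <- sweep(Z %*% t(R), 2, curve$coef, "+")
  structure(list(draws = draws, center = curve$coef, seed = seed,
                 curve_id = paste(curve$canton, curve$disease_group,
                                  curve$age_group, sep = "/")),
            class = "draw_set")
}

#' Empirical percentile interval of a statistic over coefficient draws
#'
#' @param stat_fn function mapping one coefficient vector to a scalar.
#' @param draws a [sample_coefficients()] draw set.
#' @param level interval level (default 0.95, i.e. 2.5th-97.5th percentiles).
#' @return An object of class `interval_estimate`: list with `point`
#'   (statistic at the central coefficients), `lower`, `upper`.
#' @export
empirical_interval <- function(stat_fn, draws, level = 0.95) {
  stopifnot(inherits(draws, "draw_set"))
  vals <- apply(draws$draws, 1, stat_fn)
  qs <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(point = stat_fn(draws$center),
                 lower = qs[1], upper = qs[2]),
            class = "interval_estimate")
}
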