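# Internal helpers: seed streams, date utilities, small numerics.

#' Derive a reproducible substream seed from a master seed
#'
#' Each source of randomness in the package (one canton's weather, one
#' stratum's counts, one stratum's Monte Carlo draws, ...) draws its own seed
#' deterministically from a single master seed plus a character label, so a
#' whole pipeline run is reproducible from one integer while streams stay
#' independent of evaluation order.
#'
#' @param master integer master seed.
#' @param label character scalar naming the stream.
#' @return An integer seed in [0, 2^31 - 1).
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  # polynomial rolling hash over the label bytes, folded with the master seed
  h <- 2166136261 %% 2147483647
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
  as.integer((h + abs(master) * 48271) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Sequence of calendar dates covering whole years
#' @param years integer vector of calendar years (need not be contiguous in
#'   input; output covers min..max inclusive).
#' @return A `Date` vector, one entry per day.
#' @keywords internal
year_dates <- function(years) {
  stopifnot(length(years) >= 1, all(is.finite(years)))
  seq(as.Date(sprintf("%d-01-01", min(years))),
      as.Date(sprintf("%d-12-31", max(years))), by = "day")
}

# Fixed-date Swiss national holidays used for the calendar adjustment.
holiday_dates_default <- function(years) {
  mmdd <- c("01-01", "01-02", "08-01", "12-25", "12-26")
  as.Date(unlist(lapply(min(years):max(years),
                        function(y) paste0(y, "-", mmdd))))
}

is_warm_season <- function(dates) {
  m <- as.integer(format(dates, "%m"))
  m >= 5L & m <= 9L
}

# Symmetrize and clip eigenvalues so a covariance is usable for chol/sampling.
nearest_psd <- function(V, eps = 1e-10) {
  V <- (V + t(V)) / 2
  e <- eigen(V, symmetric = TRUE)
  if (all(e$values >= -eps * max(abs(e$values), 1))) return(V)
  lam <- pmax(e$values, 0)
  V2 <- e$vectors %*% (lam * t(e$vectors))
  (V2 + t(V2)) / 2
}

is_psd <- function(V, tol = 1e-8) {
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev >= -tol * max(abs(ev), 1))
}
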