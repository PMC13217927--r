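# Second-stage pooling: multivariate meta-regression of the stratum
# cumulative exposure-response coefficients for one disease group, with age
# fixed effects, canton-level random effects (unstructured between-canton
# covariance, REML) and cantonal meta-predictors, plus best linear unbiased
# predictions per stratum.

#' Assemble the second-stage dataset for one disease group
#'
#' @param curves list of [reduced_curve()] objects (one per included canton x
#'   age stratum) sharing a basis specification.
#' @param predictors data.frame with one row per canton: `canton`,
#'   `med_warm_temp` (cantonal warm-season median Tmax, degrees C),
#'   `total_count` (total hospitalisations, entered as log10). Both
#'   predictors are mean-centered internally for scale stability.
#' @return An object of class `meta_dataset`.
#' @export
meta_dataset <- function(curves, predictors) {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, TRUE, "reduced_curve")),
            all(c("canton", "med_warm_temp", "total_count")
                %in% names(predictors)))
  k <- length(curves[[1]]$coef)
  if (!all(vapply(curves, function(cu) length(cu$coef), 1L) == k))
    stop("all curves must share one basis dimension")
  canton <- vapply(curves, function(cu) cu$canton, character(1))
  age <- vapply(curves, function(cu) cu$age_group, character(1))
  if (anyNA(canton) || anyNA(age))
    stop("curves must carry canton and age_group labels")
  miss <- setdiff(canton, predictors$canton)
  if (length(miss)) stop("predictors missing for canton(s): ",
                         paste(unique(miss), collapse = ", "))
  theta <- do.call(rbind, lapply(curves, function(cu) cu$coef))
  S <- lapply(curves, function(cu) cu$vcov)
  pr <- predictors[match(canton, predictors$canton), ]
  z1 <- pr$med_warm_temp - mean(predictors$med_warm_temp)
  z2 <- log10(pr$total_count) - mean(log10(predictors$total_count))
  structure(list(theta = theta, S = S, canton = canton,
                 age_group = factor(age), z_temp = z1, z_count = z2,
                 k = k, curves = curves),
            class = "meta_dataset")
}

# Per-stratum fixed-effect design row: intercept, age contrasts, predictors.
meta_design <- function(data) {
  ag <- droplevels(data$age_group)
  m <- if (nlevels(ag) > 1L) {
    stats::model.matrix(~ age_group, data = data.frame(age_group = ag))
  } else {
    matrix(1, length(ag), 1, dimnames = list(NULL, "(Intercept)"))
  }
  cbind(m, z_temp = data$z_temp, z_count = data$z_count)
}

# Marginal covariance of the stacked theta vector of one canton:
# shared random effect => (J_m x Psi) + blockdiag(S_i).
canton_marginal_V <- function(Psi, S_list) {
  m <- length(S_list); k <- nrow(Psi)
  V <- kronecker(matrix(1, m, m), Psi)
  for (i in seq_len(m)) {
    idx <- (i - 1L) * k + seq_len(k)
    V[idx, idx] <- V[idx, idx] + S_list[[i]]
  }
  V
}

# -2 * restricted log-likelihood (up to a constant) with profiled-out fixed
# effects, and the GLS solution, for a given Psi.
reml_objective <- function(Psi, parts) {
  pk <- ncol(parts[[1]]$X)
  A <- matrix(0, pk, pk); b <- numeric(pk)
  pieces <- lapply(parts, function(p) {
    V <- canton_marginal_V(Psi, p$S)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Vi_X <- backsolve(ch, forwardsolve(t(ch), p$X))
    Vi_y <- backsolve(ch, forwardsolve(t(ch), p$y))
    list(logdet = 2 * sum(log(diag(ch))), ch = ch,
         XtViX = crossprod(p$X, Vi_X), XtViy = crossprod(p$X, Vi_y))
  })
  if (any(vapply(pieces, is.null, TRUE))) return(list(nll = 1e10))
  for (pc in pieces) { A <- A + pc$XtViX; b <- b + pc$XtViy }
  Ach <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(Ach)) return(list(nll = 1e10))
  beta <- backsolve(Ach, forwardsolve(t(Ach), b))
  quad <- 0; logdets <- 0
  for (i in seq_along(parts)) {
    r <- parts[[i]]$y - parts[[i]]$X %*% beta
    w <- forwardsolve(t(pieces[[i]]$ch), r)
    quad <- quad + sum(w^2)
    logdets <- logdets + pieces[[i]]$logdet
  }
  nll <- logdets + 2 * sum(log(diag(Ach))) + quad
  list(nll = nll, beta = as.numeric(beta), A = A)
}

chol_from_par <- function(par, k, diagonal = FALSE) {
  L <- matrix(0, k, k)
  diag(L) <- exp(par[seq_len(k)])
  if (!diagonal && k > 1)
    L[lower.tri(L)] <- par[-seq_len(k)]
  L
}

#' Fit the multivariate meta-regression for one disease group
#'
#' Restricted maximum likelihood over the between-canton covariance `Psi`
#' (parameterised through its Cholesky factor) with fixed effects profiled
#' out by generalised least squares. Age groups enter as fixed effects on
#' every basis coefficient; cantons share an unstructured random effect on
#' the full coefficient vector; cantonal median warm-season temperature and
#' log10 total hospitalisations are meta-predictors. Falls back to a
#' diagonal `Psi` if the unstructured optimisation fails to converge.
#'
#' @param data a [meta_dataset()].
#' @param ridge relative ridge added to a within-stratum covariance whose
#'   smallest eigenvalue is not positive (with a warning).
#' @return An object of class `meta_fit` with `beta` (k x p fixed-effect
#'   matrix), `vcov_beta`, `Psi`, `nll` trace and the design metadata.
#' @export
fit_meta <- function(data, ridge = 1e-8) {
  stopifnot(inherits(data, "meta_dataset"))
  if (nrow(data$theta) < 2L || length(unique(data$canton)) < 2L)
    stop("degenerate meta-regression input: need >= 2 cantons with strata")
  if (!all(is.finite(c(data$z_temp, data$z_count))))
    stop("meta-predictors must be finite")
  k <- data$k
  S <- lapply(data$S, function(Si) {
    ev <- eigen(Si, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      warning("singular within-stratum covariance; ridge-regularizing")
      Si + diag(ridge * max(ev, 1), k)
    } else Si
  })
  Xrows <- meta_design(data)
  qrx <- qr(Xrows)
  if (qrx$rank < ncol(Xrows)) {
    drop <- setdiff(seq_len(ncol(Xrows)), qrx$pivot[seq_len(qrx$rank)])
    warning("dropping collinear meta-regression column(s): ",
            paste(colnames(Xrows)[drop], collapse = ", "))
    Xrows <- Xrows[, -drop, drop = FALSE]
  }
  p <- ncol(Xrows)
  parts <- lapply(split(seq_along(data$canton), data$canton), function(idx) {
    list(X = do.call(rbind, lapply(idx, function(i)
           kronecker(Xrows[i, , drop = FALSE], diag(k)))),
         y = as.numeric(t(data$theta[idx, , drop = FALSE])),
         S = S[idx], idx = idx)
  })
  mean_diag <- mean(unlist(lapply(S, diag)))
  obj <- function(par, diagonal) {
    L <- chol_from_par(par, k, diagonal)
    reml_objective(tcrossprod(L), parts)$nll
  }
  start_full <- c(rep(log(sqrt(0.5 * mean_diag)), k), rep(0, k * (k - 1) / 2))
  opt <- tryCatch(
    stats::optim(start_full, obj, diagonal = FALSE, method = "L-BFGS-B",
                 lower = c(rep(-15, k), rep(-30, k * (k - 1) / 2)),
                 upper = c(rep(10, k), rep(30, k * (k - 1) / 2)),
                 control = list(maxit = 500)),
    error = function(e) NULL)
  diagonal <- FALSE
  if (is.null(opt) || opt$convergence != 0) {
    diagonal <- TRUE
    opt <- stats::optim(start_full[seq_len(k)], obj, diagonal = TRUE,
                        method = "L-BFGS-B", lower = rep(-15, k),
                        upper = rep(10, k), control = list(maxit = 500))
    if (opt$convergence != 0)
      stop("meta-regression REML did not converge (final -2RL = ",
           format(opt$value), ")")
  }
  L <- chol_from_par(opt$par, k, diagonal)
  Psi <- tcrossprod(L)
  sol <- reml_objective(Psi, parts)
  structure(list(beta = matrix(sol$beta, nrow = k,
                               dimnames = list(NULL, colnames(Xrows))),
                 vcov_beta = solve(sol$A), Psi = Psi,
                 nll = opt$value, diagonal = diagonal,
                 age_levels = levels(data$age_group), k = k, p = p,
                 data = data, parts = parts, Xrows = Xrows),
            class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  cat("Multivariate meta-regression fit: k =", x$k, "basis coefficients,",
      nrow(x$data$theta), "strata,", length(unique(x$data$canton)),
      "cantons\n")
  cat("  between-canton covariance (Psi) diagonal:",
      paste(format(diag(x$Psi), digits = 3), collapse = " "), "\n")
  invisible(x)
}

# Fixed-effect prediction (k-vector) for stratum i of the fitted dataset.
fixed_prediction <- function(fit, i) {
  as.numeric(fit$beta %*% fit$Xrows[i, ])
}

#' Best linear unbiased predictions per stratum
#'
#' Empirical-Bayes conditional means: for each canton the shared random
#' effect is `u = Psi Z' V^-1 (theta - X beta)` with `V = Z Psi Z' + S`, so a
#' stratum's BLUP shrinks its first-stage estimate toward the fixed-effect
#' prediction by an amount governed by the relative sizes of the
#' within-stratum covariance and the between-canton heterogeneity. BLUP
#' covariances combine fixed-effect uncertainty with the conditional
#' random-effect covariance.
#'
#' @param fit a [fit_meta()] result.
#' @return A list of `reduced_curve` objects (additional class
#'   `blup_curve`), in the order of the input dataset.
#' @export
compute_blups <- function(fit) {
  stopifnot(inherits(fit, "meta_fit"))
  data <- fit$data
  k <- fit$k
  out <- vector("list", nrow(data$theta))
  for (part in fit$parts) {
    m <- length(part$idx)
    V <- canton_marginal_V(fit$Psi, part$S)
    Vi <- solve(V)
    Zt <- kronecker(matrix(1, 1, m), diag(k))   # Z' for shared effect
    r <- part$y - part$X %*% as.numeric(fit$beta)
    u <- fit$Psi %*% Zt %*% Vi %*% r
    cond_var <- fit$Psi - fit$Psi %*% Zt %*% Vi %*% t(Zt) %*% fit$Psi
    for (jj in seq_len(m)) {
      i <- part$idx[jj]
      mu_fix <- fixed_prediction(fit, i)
      Xi <- kronecker(fit$Xrows[i, , drop = FALSE], diag(k))
      Vstar <- Xi %*% fit$vcov_beta %*% t(Xi) + cond_var
      cu <- data$curves[[i]]
      out[[i]] <- reduced_curve(coef = mu_fix + as.numeric(u),
                                vcov = nearest_psd(Vstar),
                                spec = cu$spec, hist_max = cu$hist_max,
                                canton = cu$canton,
                                disease_group = cu$disease_group,
                                age_group = cu$age_group)
      class(out[[i]]) <- c("blup_curve", class(out[[i]]))
    }
  }
  out
}
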