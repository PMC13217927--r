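# Multivariate meta-regression and BLUPs.

# Curves for a 6-canton design from given theta rows.
curves_from_theta <- function(theta, S = diag(1e-2, ncol(theta)),
                              cantons = rep(c("BE", "BS", "GE", "TI", "VD",
                                              "ZH"),
                                            length.out = nrow(theta)),
                              ages = rep("15-74", nrow(theta))) {
  lapply(seq_len(nrow(theta)), function(i)
    make_curve(coef = theta[i, ],
               vcov = if (is.list(S)) S[[i]] else S,
               canton = cantons[i], age_group = ages[i]))
}

pred6 <- data.frame(canton = c("BE", "BS", "GE", "TI", "VD", "ZH"),
                    med_warm_temp = c(21, 22, 22.5, 24, 21.5, 21.8),
                    total_count = c(2e5, 1e5, 1.2e5, 8e4, 1.5e5, 3e5))

test_that("homogeneous strata give zero heterogeneity and reproduce the common curve", {
  theta <- matrix(rep(c(0.1, 0.2, 0.05), each = 6), nrow = 6)
  md <- meta_dataset(curves_from_theta(theta), pred6)
  fit <- fit_meta(md)
  expect_lt(max(abs(fit$Psi)), 1e-6)
  bl <- compute_blups(fit)
  for (b in bl) expect_equal(b$coef, c(0.1, 0.2, 0.05), tolerance = 1e-4)
})

test_that("a single stratum is rejected as a degenerate meta input", {
  md <- meta_dataset(curves_from_theta(matrix(c(0.1, 0.2, 0.05), 1)),
                     pred6[1, ])
  expect_error(fit_meta(md), "degenerate")
})

test_that("BLUPs reduce to the stratum estimate as within-variance vanishes", {
  set.seed(5)
  theta <- matrix(rnorm(18, sd = 0.3), nrow = 6)
  S <- c(list(diag(1e-10, 3)), replicate(5, diag(1e-2, 3), simplify = FALSE))
  md <- meta_dataset(curves_from_theta(theta, S = S), pred6)
  fit <- suppressWarnings(fit_meta(md))
  bl <- compute_blups(fit)
  expect_equal(bl[[1]]$coef, theta[1, ], tolerance = 1e-3)
})

test_that("BLUP components interpolate between stratum estimate and fixed prediction (diagonal case)", {
  # white-box construction of a meta fit with known diagonal Psi and beta
  k <- 3
  set.seed(99)
  for (rep in 1:1000) {
    theta <- rnorm(k, sd = 1)
    beta <- matrix(rnorm(k, sd = 0.5), nrow = k)   # intercept-only design
    Psi <- diag(exp(rnorm(k)), k)
    S <- diag(exp(rnorm(k)), k)
    Xrows <- matrix(1, 1, 1)
    parts <- list(list(X = kronecker(Xrows, diag(k)), y = theta,
                       S = list(S), idx = 1L))
    curves <- curves_from_theta(matrix(theta, 1), S = S)
    data <- structure(list(theta = matrix(theta, 1), S = list(S),
                           canton = "BE", age_group = factor("15-74"),
                           z_temp = 0, z_count = 0, k = k, curves = curves),
                      class = "meta_dataset")
    fit <- structure(list(beta = beta, vcov_beta = diag(1e-12, k), Psi = Psi,
                          age_levels = "15-74", k = k, p = 1, data = data,
                          parts = parts, Xrows = Xrows),
                     class = "meta_fit")
    bl <- compute_blups(fit)[[1]]
    fixd <- as.numeric(beta)
    expect_true(all(abs(bl$coef - fixd) <= abs(theta - fixd) + 1e-12))
  }
})

test_that("the REML fit agrees with an independent meta-analysis implementation (univariate)", {
  set.seed(31)
  cantons <- pred6$canton
  ages <- c("0-14", "15-74", "75+")
  vi <- runif(18, 0.01, 0.03)
  canton_i <- rep(cantons, each = 3)
  age_i <- rep(ages, 6)
  u <- rnorm(6, 0, 0.1)
  yi <- 0.2 + 0.1 * (age_i == "15-74") + 0.15 * (age_i == "75+") +
    u[match(canton_i, cantons)] + rnorm(18, 0, sqrt(vi))
  curves <- lapply(1:18, function(i)
    make_curve(coef = yi[i], vcov = matrix(vi[i], 1, 1),
               canton = canton_i[i], age_group = age_i[i]))
  f <- fit_meta(meta_dataset(curves, pred6))
  z1 <- pred6$med_warm_temp[match(canton_i, pred6$canton)] -
    mean(pred6$med_warm_temp)
  z2 <- log10(pred6$total_count[match(canton_i, pred6$canton)]) -
    mean(log10(pred6$total_count))
  rf <- metafor::rma.mv(yi, vi, mods = ~ factor(age_i) + z1 + z2,
                        random = ~ 1 | canton_i, method = "REML")
  expect_equal(as.numeric(f$beta), as.numeric(rf$beta), tolerance = 1e-5)
  expect_equal(f$Psi[1, 1], rf$sigma2, tolerance = 1e-4)
  expect_equal(sqrt(diag(f$vcov_beta)), as.numeric(rf$se), tolerance = 1e-5)
})

test_that("fixed effects and their uncertainty are recovered on simulated 6x3 designs", {
  k <- 2
  cantons <- c("BE", "BS", "GE", "TI", "VD", "ZH")
  ages <- c("0-14", "15-74", "75+")
  beta_true <- cbind(int = c(0.10, 0.05), age2 = c(0.05, 0.00),
                     age3 = c(0.10, -0.02), z1 = c(0.02, 0.01),
                     z2 = c(0.00, 0.00))
  Psi_true <- diag(c(0.03, 0.02)^2)
  S_w <- diag(c(0.04, 0.03)^2)
  z1 <- pred6$med_warm_temp - mean(pred6$med_warm_temp)
  z2 <- log10(pred6$total_count) - mean(log10(pred6$total_count))
  cover <- 0; total <- 0
  set.seed(2024)
  for (r in 1:100) {
    curves <- list()
    for (ci in seq_along(cantons)) {
      u <- as.numeric(chol(Psi_true) %*% rnorm(k))
      for (ai in seq_along(ages)) {
        x <- c(1, ai == 2, ai == 3, z1[ci], z2[ci])
        th <- as.numeric(beta_true %*% x) + u +
          as.numeric(chol(S_w) %*% rnorm(k))
        curves[[length(curves) + 1L]] <-
          make_curve(coef = th, vcov = S_w, spec = toy_spec(),
                     canton = cantons[ci], age_group = ages[ai])
      }
    }
    fit <- fit_meta(meta_dataset(curves, pred6))
    est <- fit$beta[, "(Intercept)"]
    se <- sqrt(diag(fit$vcov_beta))[1:k]
    cover <- cover + sum(abs(est - beta_true[, "int"]) <= 2 * se)
    total <- total + k
  }
  expect_gte(cover / total, 0.90)
})
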