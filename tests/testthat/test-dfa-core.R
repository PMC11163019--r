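test_that("Kalman log-likelihood equals the brute-force joint-normal oracle", {
  for (st in c("diagonal_equal", "equalvarcov", "diagonal_unequal")) {
    for (miss in c("none", "random")) {
      truth <- dfa_truth(S = 5, T = 6, m = 2, obs_sd = 3, obs_cov = 2,
                         offsets = 0, missing = miss,
                         missing_frac = 0.15, seed = 3)
      pan <- center_panel(simulate_panel(truth)$panel)
      fit <- fit_dfa(pan, m = 2, R = st,
                     control = dfa_control(max_iter = 1500))
      expect_lt(abs(fit$logLik - loglik_exact(pan, fit)), 1e-6)
    }
  }
})

test_that("with zero loadings the likelihood is a product of independent normals", {
  y <- matrix(rnorm(12, 0, 2), 3, 4)
  y <- y - rowMeans(y)
  params <- list(Z = matrix(0, 3, 1), R = diag(rep(4, 3)), x0 = 0)
  expect_equal(loglik_exact(y, params),
               sum(dnorm(y, 0, 2, log = TRUE)), tolerance = 1e-10)
})

test_that("compiled and reference filters agree on states and likelihood", {
  truth <- dfa_truth(S = 6, T = 15, m = 2, obs_sd = 3, offsets = 0,
                     missing = "random", missing_frac = 0.2, seed = 8)
  pan <- center_panel(simulate_panel(truth)$panel)
  y <- pan$values
  Z <- salmosync:::.init_Z(y, 2)
  Rm <- diag(rep(4, 6))
  kc <- salmosync:::.dfa_kalman(y, Z, Rm, c(0.1, -0.2))
  kr <- salmosync:::.dfa_kalman_r(y, Z, Rm, c(0.1, -0.2))
  expect_equal(kc$loglik, kr$loglik, tolerance = 1e-10)
  expect_equal(kc$xs, kr$xs, tolerance = 1e-10)
  expect_equal(kc$Vs, kr$Vs, tolerance = 1e-10)
  expect_equal(kc$Cs, kr$Cs, tolerance = 1e-10)
})

test_that("a noise-free panel is reproduced by the fitted values", {
  truth <- dfa_truth(S = 5, T = 25, m = 1, obs_sd = 0.01, offsets = 0,
                     missing = "none", seed = 5)
  pan <- center_panel(simulate_panel(truth)$panel)
  fit <- fit_dfa(pan, m = 1, control = dfa_control(max_iter = 5000))
  expect_lt(max(abs(fitted(fit) - pan$values)), 0.1)
})

test_that("the likelihood is invariant to sign flips of a trend and its loadings", {
  truth <- dfa_truth(S = 5, T = 12, m = 2, obs_sd = 3, offsets = 0,
                     seed = 6, missing = "none")
  pan <- center_panel(simulate_panel(truth)$panel)
  y <- pan$values
  Z <- salmosync:::.init_Z(y, 2)
  Rm <- diag(rep(4, 5))
  x0 <- c(0.3, -0.1)
  ll1 <- salmosync:::.dfa_kalman(y, Z, Rm, x0, smooth = FALSE)$loglik
  Zf <- Z; Zf[, 2] <- -Zf[, 2]
  x0f <- x0; x0f[2] <- -x0f[2]
  ll2 <- salmosync:::.dfa_kalman(y, Zf, Rm, x0f, smooth = FALSE)$loglik
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("equalvarcov with zero covariance matches diagonal-equal likelihood", {
  truth <- dfa_truth(S = 4, T = 10, m = 1, obs_sd = 3, offsets = 0,
                     seed = 7, missing = "none")
  pan <- center_panel(simulate_panel(truth)$panel)
  y <- pan$values
  Z <- salmosync:::.init_Z(y, 1)
  R_eq <- salmosync:::.build_R("diagonal_equal", 5, 4)
  R_evc <- salmosync:::.build_R("equalvarcov", c(5, 0), 4)
  ll1 <- salmosync:::.dfa_kalman(y, Z, R_eq, 0, smooth = FALSE)$loglik
  ll2 <- salmosync:::.dfa_kalman(y, Z, R_evc, 0, smooth = FALSE)$loglik
  expect_equal(ll1, ll2, tolerance = 1e-6)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  for (s in 1:3) {
    truth <- dfa_truth(S = 8, T = 25, m = 2, obs_sd = 5, offsets = 0,
                       missing = "random", missing_frac = 0.2, seed = s)
    pan <- center_panel(simulate_panel(truth)$panel)
    fit <- fit_dfa(pan, m = 2, R = "equalvarcov",
                   control = dfa_control(max_iter = 400))
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
  }
})

test_that("AICc follows its formula and decreases with n at fixed K and logLik", {
  fit <- small_fit()
  K <- fit$n_params; n <- fit$n_obs
  expect_equal(fit$AICc, -2 * fit$logLik + 2 * K * n / (n - K - 1),
               tolerance = 1e-10)
  lls <- -100
  a1 <- AICc(lls, k = 10, n = 50)
  a2 <- AICc(lls, k = 10, n = 500)
  expect_gt(a1, a2)
  expect_equal(AICc(lls, k = 10, n = 1e12), -2 * lls + 20,
               tolerance = 1e-6)
})

test_that("varimax rotation leaves fitted values unchanged and H is orthogonal", {
  truth <- dfa_truth(S = 8, T = 30, m = 3, obs_sd = 4, offsets = 0,
                     seed = 10, missing = "none")
  pan <- center_panel(simulate_panel(truth)$panel)
  fit <- fit_dfa(pan, m = 3, control = dfa_control(max_iter = 1500))
  rot <- varimax_rotate(fit)
  expect_lt(max(abs(fitted(rot) - fitted(fit))), 1e-10)
  H <- rot$rotation
  expect_lt(max(abs(crossprod(H) - diag(3))), 1e-10)

  fit1 <- small_fit()
  one <- fit_dfa(fit1$panel, m = 1, control = dfa_control(max_iter = 500))
  rot1 <- varimax_rotate(one)
  expect_identical(rot1$Z, one$Z)
})

test_that("confidence bands widen with level and match the state covariance", {
  fit <- small_fit()
  f95 <- fitted_ci(fit, 0.95)
  f99 <- fitted_ci(fit, 0.99)
  expect_true(all(f99$upper - f99$lower > f95$upper - f95$lower))
  # delta-method width: 2 * z * sqrt(z_i' V_t z_i)
  i <- 3; t <- 7
  se_manual <- sqrt(drop(t(fit$Z[i, ]) %*% fit$x_var[, , t] %*%
                           fit$Z[i, ]))
  row <- f95[f95$river == rownames(fit$Z)[i] &
               f95$year == fit$panel$years[t], ]
  expect_equal(row$se, se_manual, tolerance = 1e-10)
})

test_that("trend bands cover a low-noise truth at close to nominal rate", {
  cover <- numeric(0)
  for (s in 1:4) {
    truth <- dfa_truth(S = 8, T = 30, m = 1, obs_sd = 1, offsets = 0,
                       missing = "none", seed = 100 + s)
    sim <- simulate_panel(truth)
    pan <- center_panel(sim$panel)
    fit <- fit_dfa(pan, m = 1, control = dfa_control(max_iter = 3000))
    fc <- fitted_ci(fit, 0.95)
    truth_centered <- truth$loadings %*% truth$trends
    truth_centered <- truth_centered - rowMeans(truth_centered)
    inside <- fc$fitted * 0
    tv <- as.vector(truth_centered)  # river-major within year, as fc
    cover <- c(cover, mean(tv >= fc$lower & tv <= fc$upper))
  }
  # bands condition on the estimated loadings, so mild undercoverage
  # relative to the nominal 95% is expected
  expect_gt(mean(cover), 0.75)
})

test_that("a degenerate all-zero covariate reproduces the base fit with a pure parameter penalty", {
  truth <- dfa_truth(S = 5, T = 20, m = 1, obs_sd = 4, offsets = 0,
                     seed = 12, missing = "none")
  pan <- center_panel(simulate_panel(truth)$panel)
  base <- fit_dfa(pan, m = 1, control = dfa_control(max_iter = 1500))
  suppressWarnings(
    fit0 <- fit_dfa(pan, m = 1, covariates = rep(0, 20),
                    control = dfa_control(max_iter = 1500, d_se = FALSE)))
  expect_equal(fit0$logLik, base$logLik, tolerance = 1e-5)
  n <- base$n_obs; K0 <- base$n_params; K1 <- fit0$n_params
  expect_equal(K1 - K0, 5L)
  penalty <- 2 * K1 * n / (n - K1 - 1) - 2 * K0 * n / (n - K0 - 1)
  expect_equal(fit0$AICc - base$AICc, penalty, tolerance = 1e-4)
})

test_that("an injected covariate effect is recovered with calibrated intervals", {
  hits_target <- 0; hits_null <- 0; n_null <- 0
  for (s in 1:5) {
    truth <- dfa_truth(S = 8, T = 40, m = 1, obs_sd = 5, offsets = 0,
                       missing = "none", seed = 200 + s)
    sim <- simulate_panel(truth)
    dcv <- simulate_covariates(years = truth$years, ar_coef = 0.5,
                               names = "d", seed = 300 + s)
    dsc <- as.numeric(scale(dcv$d))
    yv <- sim$panel$values
    yv[1, ] <- yv[1, ] + 10 * dsc      # 10 mm per SD on river 1 only
    pan <- center_panel(length_panel(yv, truth$years,
                                     sim$panel$rivers))
    fit <- fit_dfa(pan, m = 1, covariates = dsc,
                   control = dfa_control(max_iter = 2000))
    ci <- fit$D_ci
    if (ci[1, 1, "lower"] <= 10 && ci[1, 1, "upper"] >= 10) {
      hits_target <- hits_target + 1
    }
    others <- ci[-1, 1, "lower"] <= 0 & ci[-1, 1, "upper"] >= 0
    hits_null <- hits_null + sum(others); n_null <- n_null + length(others)
  }
  expect_gte(hits_target, 3)          # majority of seeds
  expect_gte(hits_null / n_null, 0.7) # most null rivers' CIs include 0
})

test_that("fit_dfa validates its inputs", {
  truth <- dfa_truth(S = 4, T = 10, m = 1, obs_sd = 3, seed = 1)
  pan <- center_panel(simulate_panel(truth)$panel)
  expect_error(fit_dfa(pan, m = 4), "less than the number of rivers")
  yv <- pan$values; yv[2, ] <- NA
  pan2 <- length_panel(yv, pan$years, pan$rivers, centered = FALSE)
  expect_error(fit_dfa(pan2, m = 1), "all-missing river")
  expect_error(fit_dfa(pan, m = 1, covariates = c(NA, rnorm(9))),
               "complete")
})
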