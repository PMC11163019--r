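make_fc <- function(river, years, fitted, half_width, centered = TRUE,
                    river_means = NULL) {
  fc <- data.frame(river = river, year = years, fitted = fitted,
                   se = half_width / qnorm(0.975))
  fc$lower <- fitted - half_width
  fc$upper <- fitted + half_width
  attr(fc, "centered") <- centered
  attr(fc, "level") <- 0.95
  attr(fc, "river_means") <- river_means
  fc
}

test_that("the significance rule needs excluding-zero runs of both signs", {
  yrs <- 1971:2000
  # CIs straddle zero everywhere -> not significant
  fc0 <- make_fc("r1", yrs, fitted = rep(0.5, 30), half_width = 2)
  rep0 <- significant_changes(fc0)
  expect_false(rep0$summary$significant)
  expect_equal(nrow(rep0$runs), 0L)

  # below 1975-1985, above 1995-2000 -> significant positive change
  fit_vals <- c(seq(-30, -30, length.out = 5), rep(-30, 10),
                seq(-30, 40, length.out = 9), rep(40, 6))
  hw <- rep(10, 30)
  fc1 <- make_fc("r1", yrs, fit_vals, hw,
                 river_means = c(r1 = 500))
  rep1 <- significant_changes(fc1)
  expect_true(rep1$summary$significant)
  expect_equal(rep1$summary$change_mm, 70)
  expect_equal(rep1$summary$change_pct, 14)
  expect_setequal(rep1$runs$direction, c("above", "below"))
  # runs are disjoint and maximal
  expect_true(all(rep1$runs$start_year <= rep1$runs$end_year))

  # two "above" runs but no "below": not significant under the default
  # both-signs rule, significant under the any-two-runs relaxation
  fc2 <- make_fc("r1", yrs, c(rep(0, 10), rep(30, 5), rep(0, 5),
                              rep(30, 10)), rep(5, 30))
  expect_false(significant_changes(fc2)$summary$significant)
  expect_true(significant_changes(fc2,
                                  require_both_signs = FALSE)$summary$significant)
  # a single run is never "two periods", under either rule
  fc3 <- make_fc("r1", yrs, c(rep(0, 20), rep(30, 10)), rep(5, 30))
  expect_false(significant_changes(fc3)$summary$significant)
  expect_false(significant_changes(fc3,
                                   require_both_signs = FALSE)$summary$significant)
})

test_that("the significance rule refuses fitted values that are not centered", {
  fc <- make_fc("r1", 1971:1980, rep(550, 10), rep(5, 10),
                centered = FALSE)
  expect_error(significant_changes(fc), "centered")
})

test_that("aicc_threshold is twice the number of series", {
  expect_equal(aicc_threshold(19), 38)
  expect_equal(aicc_threshold(8), 16)
  expect_equal(aicc_threshold(1), 2)
})

test_that("model selection produces a coherent, deterministic AICc table", {
  truth <- dfa_truth(S = 6, T = 30, m = 1,
                     loadings = matrix(runif(6, 1, 3), 6, 1),
                     obs_sd = 5, offsets = 0, seed = 21,
                     missing = "none")
  pan <- center_panel(simulate_panel(truth)$panel)
  sel <- select_model(pan, m_range = 1:2,
                      structures = c("diagonal_equal", "equalvarcov"),
                      control = dfa_control(max_iter = 1500))
  tab <- sel$table
  conv <- tab[tab$converged, ]
  expect_equal(sum(conv$weight), 1, tolerance = 1e-9)
  expect_true(all(conv$dAICc >= 0))
  expect_equal(sum(conv$dAICc == 0), 1L)
  expect_true(sel$fit$rotated)

  sel2 <- select_model(pan, m_range = 1:2,
                       structures = c("diagonal_equal", "equalvarcov"),
                       control = dfa_control(max_iter = 1500))
  expect_identical(sel$table, sel2$table)
  expect_identical(sel$fit$Z, sel2$fit$Z)
})

test_that("loading clusters: one tight blob gives k = 1, two separated blobs give k = 2", {
  set.seed(5)
  Z1 <- matrix(rep(c(1, -0.5), each = 12), 12, 2) +
    matrix(rnorm(24, 0, 0.01), 12, 2)
  cl1 <- cluster_loadings(Z1, B = 50, seed = 1)
  expect_equal(cl1$k, 1L)

  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    blob1 <- matrix(rnorm(16, 0, 0.15), 8, 2) +
      matrix(rep(c(2, 2), each = 8), 8, 2)
    blob2 <- matrix(rnorm(16, 0, 0.15), 8, 2) +
      matrix(rep(c(-2, -2), each = 8), 8, 2)
    cl2 <- cluster_loadings(rbind(blob1, blob2), B = 50, seed = s)
    hits <- hits + (cl2$k == 2L)
  }
  expect_gte(hits, 4)

  expect_error(cluster_loadings(matrix(1:5, 5, 1)), "at least two")
})

test_that("the complete-linkage root height equals the maximum pairwise distance", {
  set.seed(9)
  Z <- matrix(rnorm(30), 10, 3)
  cl <- cluster_loadings(Z, B = 10, seed = 2)
  dmax <- max(dist(scale(Z)))
  expect_equal(max(cl$hclust$height), dmax, tolerance = 1e-10)
})

test_that("gap statistic finds a single cluster in one isotropic Gaussian", {
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    Z <- matrix(rnorm(24), 12, 2)
    cl <- cluster_loadings(Z, B = 50, seed = s)
    hits <- hits + (cl$k == 1L)
  }
  expect_gte(hits, 3)   # majority of seeds
})

test_that("pure-noise covariates do not improve the base model", {
  worse <- 0
  for (s in 1:4) {
    truth <- dfa_truth(S = 6, T = 30, m = 1,
                       loadings = matrix(runif(6, 1, 3), 6, 1),
                       obs_sd = 5, offsets = 0, seed = 400 + s,
                       missing = "none")
    pan <- center_panel(simulate_panel(truth)$panel)
    base <- fit_dfa(pan, m = 1, control = dfa_control(max_iter = 1500))
    cvs <- simulate_covariates(years = truth$years, ar_coef = 0,
                               names = "noise", seed = 500 + s)
    cvs <- center_scale(cvs)
    ev <- evaluate_covariates(pan, base, cvs,
                              control = dfa_control(max_iter = 1500,
                                                    d_se = FALSE))
    worse <- worse + (ev$table$dAICc[1] > 0)
    expect_equal(ev$threshold, 12)  # 2 x 6 rivers
  }
  expect_gte(worse, 3)

  # misaligned covariate years are an error
  truth <- dfa_truth(S = 5, T = 10, m = 1, obs_sd = 4, seed = 1)
  pan <- center_panel(simulate_panel(truth)$panel)
  base <- fit_dfa(pan, m = 1, control = dfa_control(max_iter = 300))
  bad <- data.frame(year = 1800:1809, x = rnorm(10))
  expect_error(evaluate_covariates(pan, base, bad), "cover")
})
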