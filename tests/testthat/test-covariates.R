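test_that("climate means use the right windows and year labels", {
  mon <- expand.grid(month = 1:12, year = 1990:1992)
  mon$value <- 3
  expect_true(all(climate_means(mon, "Jan-Dec")$value == 3))

  # Dec 1990 + Jan-Mar 1991 = {1,1,1,5} -> 1991 mean 2
  mon2 <- mon
  mon2$value[mon2$year == 1990 & mon2$month == 12] <- 5
  mon2$value[mon2$year == 1991 & mon2$month %in% 1:3] <- 1
  nao <- climate_means(mon2, "Dec-Mar")
  expect_equal(nao$value[nao$year == 1991], 2)

  # a pure seasonal cycle has zero annual mean
  mon3 <- expand.grid(month = 1:12, year = 2000:2004)
  mon3$value <- sin(2 * pi * mon3$month / 12)
  jd <- climate_means(mon3, "Jan-Dec")
  expect_true(all(abs(jd$value) < 1e-12))
})

test_that("the food index is an oriented PC1 with eigenvalue-consistent variance", {
  yrs <- 2000:2019
  z <- data.frame(year = yrs, value = sin(yrs / 2) + yrs / 30)
  cap <- data.frame(year = yrs, value = 2 * z$value + 5)  # rank 1
  fi <- food_availability_index(z, cap)
  expect_equal(fi$var_explained, 1, tolerance = 1e-10)

  set.seed(1)
  n <- 5000
  a <- data.frame(year = 1:n, value = rnorm(n))
  b <- data.frame(year = 1:n, value = rnorm(n))
  fi2 <- food_availability_index(a, b)
  expect_lt(abs(fi2$var_explained - 0.5), 0.02)
  # oracle: largest correlation-matrix eigenvalue over number of series
  lam <- eigen(cor(cbind(a$value, b$value)))$values[1]
  expect_equal(fi2$var_explained, lam / 2, tolerance = 1e-10)

  # the year with the lowest biomass in both series is the most negative
  set.seed(2)
  z3 <- data.frame(year = 1:30, value = runif(30, 1, 10))
  c3 <- data.frame(year = 1:30, value = runif(30, 1, 10))
  z3$value[7] <- 0.1; c3$value[7] <- 0.1
  fi3 <- food_availability_index(z3, c3)
  expect_equal(which.min(fi3$scores$pc1), 7L)

  expect_error(food_availability_index(z3[1:2, ], c3[1:2, ]),
               "overlapping years")
})

test_that("PFA back-adjustment is the fixed exponential factor and is linear", {
  expect_equal(adjust_pfa_to_jan(0), 0)
  expect_equal(adjust_pfa_to_jan(100), 100 * exp(0.21), tolerance = 1e-12)
  expect_equal(adjust_pfa_to_jan(100), 123.3678, tolerance = 1e-4)
  a <- 37.5; b <- 11.1
  expect_equal(adjust_pfa_to_jan(a + b),
               adjust_pfa_to_jan(a) + adjust_pfa_to_jan(b),
               tolerance = 1e-12)
  expect_error(adjust_pfa_to_jan(-1), "non-negative")
})

test_that("density indices combine stock components per sea year", {
  pfa <- data.frame(year = 2000:2002,
                    nac_maturing = c(10, 5, NA),
                    nac_nonmaturing = c(20, 15, 8),
                    sneac_nonmaturing = c(7, 3, 2))
  d1 <- density_index(pfa, "first")
  expect_equal(d1$value[1], 30 * exp(0.21), tolerance = 1e-12)
  expect_true(is.na(d1$value[3]))      # missing component propagates
  d2 <- density_index(pfa, "second")
  expect_equal(d2$value[1], 20 * exp(0.21) + 7, tolerance = 1e-12)
  # homogeneity: doubling all inputs doubles the index
  pfa2 <- pfa; pfa2[, -1] <- pfa2[, -1] * 2
  expect_equal(density_index(pfa2, "first")$value,
               2 * d1$value, tolerance = 1e-12)

  pfa_sneac <- data.frame(year = 2000, nac_maturing = 0,
                          nac_nonmaturing = 0, sneac_nonmaturing = 9)
  expect_equal(density_index(pfa_sneac, "second")$value, 9)
})

test_that("exploitation rates are proportions with the documented denominators", {
  f <- data.frame(year = 2000:2002,
                  catch_nl = c(100, 0, 50), catch_lab = c(50, 0, 25),
                  catch_spm = c(10, 0, 5),
                  catch_wg = c(200, 0, 100),
                  returns_nac_small = c(160, 300, 80),
                  returns_nac_large = c(400, 200, 100))
  pfa <- data.frame(year = 2000:2002, value = c(1000, 800, 500))
  er <- exploitation_rates(f, pfa)
  expect_equal(er$er_wg[1], 0.2)
  expect_equal(er$er_nac_small[1], 160 / (160 + 160))  # catches = returns
  expect_true(all(er$er_nac_small[2] == 0 & er$er_wg[2] == 0))
  expect_true(all(er[, -1] >= 0 & er[, -1] <= 1, na.rm = TRUE))

  # monotone in catch, returns held fixed
  f_up <- f; f_up$catch_nl <- f_up$catch_nl + 10
  er_up <- exploitation_rates(f_up, pfa)
  expect_true(all(er_up$er_nac_small >= er$er_nac_small))

  # literal catch/returns reading can exceed 1
  er_lit <- exploitation_rates(f, pfa, denominator = "returns")
  expect_equal(er_lit$er_nac_small[1], 1)
  expect_equal(er_lit$er_nac_small[3], 1)

  # zero denominator -> NA with warning
  f0 <- f; f0$returns_nac_small <- 0; f0$catch_nl[1:3] <- 0
  f0$catch_lab <- 0; f0$catch_spm <- 0
  expect_warning(er0 <- exploitation_rates(f0, pfa,
                                           denominator = "returns"))
  expect_true(all(is.na(er0$er_nac_small)))
})

test_that("center_scale produces idempotent, invertible z-scores", {
  tab <- data.frame(year = 2000:2002, a = c(1, 2, 3), b = c(5, 9, 1))
  sc <- center_scale(tab)
  expect_equal(sc$a, c(-1, 0, 1))
  expect_equal(mean(sc$b), 0, tolerance = 1e-12)
  expect_equal(sd(sc$b), 1, tolerance = 1e-12)
  expect_identical(center_scale(sc), sc)
  back <- uncenter_scale(sc)
  expect_equal(back$a, tab$a, tolerance = 1e-12)
  expect_equal(back$b, tab$b, tolerance = 1e-12)
  expect_error(center_scale(data.frame(year = 1:3, k = c(2, 2, 2))),
               "constant")
})
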