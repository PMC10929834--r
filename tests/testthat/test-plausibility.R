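wfit2 <- function(lam, rho, se_lam = 20, se_rho = 0.5, study_id = "x") {
  structure(list(lam = lam, rho = rho, se_lam = se_lam, se_rho = se_rho,
                 study_id = study_id), class = "weibull_fit")
}

test_that("weighted reference moments match the closed formulas", {
  # equal weights: mean is arithmetic, corrected variance is the usual
  # unbiased sample variance
  lam <- c(800, 850, 900, 870, 830)
  rho <- c(5, 6, 7, 5.5, 6.5)
  fits <- Map(wfit2, lam, rho)
  ref <- estimate_reference(fits)
  expect_equal(unname(ref$mean), c(mean(lam), mean(rho)))
  expect_equal(ref$cov[1, 1], var(lam))
  expect_equal(ref$cov[2, 2], var(rho))
  expect_equal(ref$cov[1, 2], cov(lam, rho))

  # unequal weights: evaluate the reliability-weighted formulas directly
  se_lam <- c(10, 20, 30, 15, 25); se_rho <- c(0.2, 0.5, 0.4, 0.3, 0.6)
  fits2 <- Map(wfit2, lam, rho, se_lam, se_rho)
  ref2 <- estimate_reference(fits2)
  wl <- 1 / se_lam^2; wr <- 1 / se_rho^2
  ml <- sum(wl * lam) / sum(wl); mr <- sum(wr * rho) / sum(wr)
  vl <- sum(wl * (lam - ml)^2) / (sum(wl) - sum(wl^2) / sum(wl))
  u <- sqrt(wl * wr)
  cv <- sum(u * (lam - ml) * (rho - mr)) / (sum(u) - sum(u^2) / sum(u))
  expect_equal(unname(ref2$mean), c(ml, mr))
  expect_equal(ref2$cov[1, 1], vl)
  expect_equal(ref2$cov[1, 2], cv)
})

test_that("the two-point corrected variance matches a hand calculation", {
  # {(800, 5), (900, 7)} with equal weights: mean (850, 6) and the
  # two-point corrected variance 2 * 50^2 = 5000 (divisor n - 1 = 1)
  wv <- lifespanqc:::weighted_var
  expect_equal(sum(c(800, 900)) / 2, 850)
  expect_equal(wv(c(800, 900), c(1, 1)), 5000)
  expect_equal(wv(c(5, 7), c(1, 1)), 2)
})

test_that("an infinitely noisy study carries no weight", {
  fits <- c(list(wfit2(900, 6, se_lam = 1, se_rho = 0.01)),
            lapply(1:5, function(i) wfit2(700 + 40 * i, 4 + 0.3 * i,
                                          se_lam = 1e6, se_rho = 1e4)))
  ref <- estimate_reference(fits)
  expect_equal(unname(ref$mean), c(900, 6), tolerance = 1e-4)
})

test_that("reference estimation needs at least five studies", {
  fits <- lapply(1:4, function(i) wfit2(850 + i, 6))
  expect_error(estimate_reference(fits), "insufficient",
               class = "lifespanqc_validation_error")
})

test_that("identical reference fits trigger the ridge remedy", {
  fits <- lapply(1:6, function(i) wfit2(880, 6))
  expect_warning(ref <- estimate_reference(fits), "ridge")
  expect_true(all(eigen(ref$cov, symmetric = TRUE)$values > 0))
  res <- plausibility_test(wfit2(880, 6), ref)
  expect_equal(res$p_value, 1)
})

test_that("reference recovery from a known generating Gaussian", {
  set.seed(51)
  mu <- c(880, 6); Sg <- matrix(c(40^2, 5, 5, 0.5^2), 2)
  err_mean <- replicate(50, {
    par <- MASS::mvrnorm(20, mu, Sg)
    fits <- Map(wfit2, par[, 1], par[, 2],
                MoreArgs = list(se_lam = 1e-3, se_rho = 1e-5))
    ref <- estimate_reference(fits)
    abs(unname(ref$mean) - mu) / mu
  })
  expect_lt(mean(err_mean), 0.02)
})

test_that("the center of the reference is perfectly plausible", {
  fits <- Map(wfit2, c(800, 850, 900, 870, 830), c(5, 6, 7, 5.5, 6.5))
  ref <- estimate_reference(fits)
  res <- plausibility_test(wfit2(ref$mean[1], ref$mean[2]), ref)
  expect_equal(res$d2, 0)
  expect_equal(res$t2, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$verdict, "plausible")
})

test_that("a far outlier along the major axis is rejected", {
  set.seed(52)
  par <- MASS::mvrnorm(20, c(880, 6), diag(c(40^2, 0.5^2)))
  fits <- Map(wfit2, par[, 1], par[, 2])
  ref <- estimate_reference(fits)
  eg <- eigen(ref$cov, symmetric = TRUE)
  theta <- ref$mean + 6 * sqrt(eg$values[1]) * eg$vectors[, 1] *
    sign(eg$vectors[1, 1])
  res <- plausibility_test(wfit2(theta[1], theta[2]), ref)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$verdict, "outlier")
})

test_that("plausibility score is invariant under a days-to-weeks rescaling", {
  pop <- generate_population(8, n = 60, seed = 53)
  fits <- lapply(pop, fit_weibull)
  ref <- estimate_reference(fits)
  new <- fit_weibull(generate_population(1, n = 60, seed = 54)[[1]])
  p_days <- plausibility_test(new, ref)$p_value

  rescale <- function(f) { f$lam <- f$lam / 7; f$se_lam <- f$se_lam / 7; f }
  ref_w <- estimate_reference(lapply(fits, rescale))
  p_weeks <- plausibility_test(rescale(new), ref_w)$p_value
  expect_equal(p_days, p_weeks, tolerance = 1e-10)
})

test_that("plausibility decays monotonically along any ray from the mean", {
  fits <- Map(wfit2, c(800, 850, 900, 870, 830), c(5, 6, 7, 5.5, 6.5))
  ref <- estimate_reference(fits)
  for (dir in list(c(1, 0), c(0, 1), c(1, 1), c(2, -1))) {
    dirn <- dir / sqrt(sum(dir^2))
    p <- vapply(seq(0, 3, by = 0.5), function(r) {
      th <- ref$mean + r * dirn * c(40, 0.8)
      plausibility_test(list(lam = th[1], rho = th[2]), ref)$p_value
    }, numeric(1))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("the F and chi-squared references agree for many studies", {
  set.seed(55)
  par <- MASS::mvrnorm(200, c(880, 6), diag(c(40^2, 0.5^2)))
  fits <- Map(wfit2, par[, 1], par[, 2])
  ref <- estimate_reference(fits)
  new <- wfit2(930, 6.8)
  pf_ <- plausibility_test(new, ref, method = "hotelling_f")$p_value
  pc_ <- plausibility_test(new, ref, method = "chisq")$p_value
  expect_equal(pf_, pc_, tolerance = 0.05)
  # and the F form is the more conservative at small n
  fits_small <- Map(wfit2, par[1:6, 1], par[1:6, 2])
  ref_s <- estimate_reference(fits_small)
  expect_gte(plausibility_test(new, ref_s, method = "hotelling_f")$p_value,
             plausibility_test(new, ref_s, method = "chisq")$p_value * 0.999)
})
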