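wfit <- function(lam, rho, se_lam = 20, se_rho = 0.5, study_id = "x", n = 50) {
  structure(list(lam = lam, rho = rho, se_lam = se_lam, se_rho = se_rho,
                 cov = diag(c(se_lam^2, se_rho^2)), loglik = NA_real_,
                 n = n, n_events = n, study_id = study_id),
            class = "weibull_fit")
}

test_that("equal-precision studies combine to the arithmetic mean", {
  meta <- combine_weibull_fits(list(wfit(800, 5), wfit(900, 7)))
  expect_equal(meta$lam_bar, 850)
  expect_equal(meta$rho_bar, 6)
})

test_that("a single study passes through unchanged", {
  f <- wfit(875, 5.5, se_lam = 17, se_rho = 0.4)
  expect_message(meta <- combine_weibull_fits(list(f)), "single")
  expect_equal(meta$lam_bar, 875)
  expect_equal(meta$se_lam_bar, 17)
  expect_equal(meta$tau2_lam, 0)
  expect_equal(meta$n_studies, 1L)
})

test_that("random-effects combination matches metafor's DerSimonian-Laird", {
  skip_if_not_installed("metafor")
  set.seed(31)
  for (rep in 1:5) {
    lam <- rnorm(8, 880, 40)
    se <- runif(8, 10, 35)
    fits <- Map(function(l, s) wfit(l, 6, se_lam = s), lam, se)
    meta <- combine_weibull_fits(fits, method = "random_effects")
    rma <- metafor::rma(yi = lam, sei = se, method = "DL")
    expect_equal(meta$lam_bar, as.numeric(rma$beta), tolerance = 1e-10)
    expect_equal(meta$se_lam_bar, rma$se, tolerance = 1e-10)
    expect_equal(meta$tau2_lam, rma$tau2, tolerance = 1e-10)

    meta_fe <- combine_weibull_fits(fits, method = "fixed_effects")
    rma_fe <- metafor::rma(yi = lam, sei = se, method = "FE")
    expect_equal(meta_fe$lam_bar, as.numeric(rma_fe$beta), tolerance = 1e-10)
  }
})

test_that("DL between-study variance is recovered in simulation", {
  set.seed(32)
  tau2_hat <- replicate(200, {
    lam <- rnorm(10, 880, 40)
    se <- runif(10, 8, 15)
    obs <- lam + rnorm(10, 0, se)
    fits <- Map(function(l, s) wfit(l, 6, se_lam = s), obs, se)
    combine_weibull_fits(fits)$tau2_lam
  })
  expect_gt(median(tau2_hat), 1600 / 2)
  expect_lt(median(tau2_hat), 1600 * 2)
})

test_that("combined parameters stay in the componentwise envelope", {
  set.seed(33)
  for (rep in 1:100) {
    k <- sample(2:8, 1)
    fits <- lapply(seq_len(k), function(i) {
      wfit(runif(1, 700, 1000), runif(1, 4, 8),
           se_lam = runif(1, 5, 40), se_rho = runif(1, 0.1, 1))
    })
    meta <- combine_weibull_fits(fits,
                                 method = sample(c("random_effects",
                                                   "fixed_effects"), 1))
    lam <- vapply(fits, `[[`, numeric(1), "lam")
    rho <- vapply(fits, `[[`, numeric(1), "rho")
    expect_gte(meta$lam_bar, min(lam) - 1e-9)
    expect_lte(meta$lam_bar, max(lam) + 1e-9)
    expect_gte(meta$rho_bar, min(rho) - 1e-9)
    expect_lte(meta$rho_bar, max(rho) + 1e-9)
  }
})

test_that("fixed and random effects coincide for homogeneous studies", {
  fits <- list(wfit(880, 6), wfit(880, 6), wfit(880, 6))
  re <- combine_weibull_fits(fits, "random_effects")
  fe <- combine_weibull_fits(fits, "fixed_effects")
  expect_equal(re$tau2_lam, 0)
  expect_equal(re$lam_bar, fe$lam_bar)
  expect_equal(re$se_lam_bar, fe$se_lam_bar)
})

test_that("shrinking one study's SE pulls the estimate toward it", {
  base <- list(wfit(800, 5), wfit(900, 7))
  m0 <- combine_weibull_fits(base, "fixed_effects")
  tight <- list(wfit(800, 5, se_lam = 5), wfit(900, 7))
  m1 <- combine_weibull_fits(tight, "fixed_effects")
  expect_lt(m1$lam_bar, m0$lam_bar)
})

test_that("meta-median follows the meta-Weibull closed form", {
  meta <- combine_weibull_fits(list(wfit(900, 6), wfit(900, 6)))
  expect_equal(meta_median(meta), 900 * log(2)^(1/6))
  meta1 <- combine_weibull_fits(list(wfit(840, 1)))
  expect_equal(meta_median(meta1), 840 * log(2))
  # identical components: meta-median equals each component's median
  expect_equal(meta_median(meta), weibull_median(wfit(900, 6)))
})

test_that("null treatment effect is near zero with a covering interval", {
  meta <- combine_weibull_fits(list(wfit(880, 6, se_lam = 10, se_rho = 0.2),
                                    wfit(880, 6, se_lam = 10, se_rho = 0.2)))
  treated <- generate_cohort(n = 100, lam = 880, rho = 6, seed = 41,
                             group = "treatment")
  eff <- treatment_effect(treated, meta, n_bootstrap = 400, seed = 41)
  expect_lt(abs(eff$percent_change), 10)
  expect_lte(eff$ci_low, eff$percent_change)
  expect_gte(eff$ci_high, eff$percent_change)
  expect_true(eff$ci_low <= 0 && eff$ci_high >= 0)
  # percent change consistent with the two medians
  expect_equal(eff$percent_change,
               (eff$median_treated - eff$median_meta) / eff$median_meta * 100)
})

test_that("a 15 percent lifespan extension is recovered", {
  meta <- combine_weibull_fits(list(wfit(880, 6, se_lam = 8, se_rho = 0.15),
                                    wfit(880, 6, se_lam = 8, se_rho = 0.15)))
  treated <- generate_cohort(n = 100, lam = 880 * 1.15, rho = 6, seed = 42,
                             group = "treatment")
  eff <- treatment_effect(treated, meta, n_bootstrap = 400, seed = 42)
  expect_gte(eff$ci_low, 0)
  expect_true(eff$ci_low <= 15 && 15 <= eff$ci_high + 5)
  expect_equal(eff$percent_change, 15, tolerance = 0.5)
})

test_that("meta-control inputs are validated", {
  expect_error(combine_weibull_fits(list()), class = "lifespanqc_validation_error")
  bad <- wfit(800, 5); bad$se_lam <- -1
  expect_error(combine_weibull_fits(list(bad)),
               class = "lifespanqc_validation_error")
})
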