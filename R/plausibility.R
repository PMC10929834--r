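#' Reference distribution over Weibull parameters
#'
#' Estimates the 2-D Gaussian reference distribution `P(lambda, rho)` of
#' high-quality control cohorts from their Weibull fits, weighting each study
#' by its inverse squared standard errors. Per component the weighted mean is
#' `sum(w x)/sum(w)` with `w_i = 1/SE_i^2`, and the weighted marginal
#' variance uses the reliability-weight bias correction
#' `sum(w (x - xbar)^2) / (sum w - sum w^2 / sum w)`. The cross-covariance
#' uses pairwise weights `u_i = sqrt(w_lam_i w_rho_i)` with the analogous
#' correction, centered on the reference mean vector. A matrix that comes
#' out non-positive-definite (e.g. identical reference fits) gets a ridge of
#' `1e-6 x mean diagonal` added, with a warning.
#'
#' @param fits List of at least 5 `weibull_fit` objects with positive SEs.
#' @return A `reference_distribution`: `mean` (lambda, rho), `cov` (2x2),
#'   `n_studies`, `weights_lam`, `weights_rho`, `study_ids`.
#' @export
estimate_reference <- function(fits) {
  if (inherits(fits, "weibull_fit")) fits <- list(fits)
  if (!is.list(fits) || length(fits) < 5L) {
    abort_validation("insufficient reference studies (need >= 5 Weibull fits)")
  }
  fits <- check_fit_list(fits, min_n = 5L)
  lam <- vapply(fits, `[[`, numeric(1), "lam")
  rho <- vapply(fits, `[[`, numeric(1), "rho")
  wl <- 1 / vapply(fits, `[[`, numeric(1), "se_lam")^2
  wr <- 1 / vapply(fits, `[[`, numeric(1), "se_rho")^2
  ml <- sum(wl * lam) / sum(wl)
  mr <- sum(wr * rho) / sum(wr)
  vl <- weighted_var(lam, wl, ml)
  vr <- weighted_var(rho, wr, mr)
  u <- sqrt(wl * wr)
  cv <- sum(u * (lam - ml) * (rho - mr)) / (sum(u) - sum(u^2) / sum(u))
  S <- matrix(c(vl, cv, cv, vr), 2, 2)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  par_scale <- mean(c(ml, mr)^2)
  if (mean(diag(S)) <= 1e-12 * par_scale) {
    # all reference fits (numerically) identical: no empirical spread at all
    warning("degenerate reference covariance (identical reference fits); adding a parameter-scale ridge",
            call. = FALSE)
    S <- diag(1e-9 * par_scale, 2)
  } else if (min(ev) <= 1e-12 * max(abs(ev))) {
    ridge <- 1e-6 * mean(diag(S)) + max(0, -min(ev))
    warning(sprintf(
      "degenerate reference covariance; adding ridge %.3g to the diagonal",
      ridge), call. = FALSE)
    S <- S + diag(ridge, 2)
  }
  structure(
    list(mean = c(lam = ml, rho = mr), cov = S, n_studies = length(fits),
         weights_lam = wl, weights_rho = wr,
         study_ids = vapply(fits, function(f) as.character(f$study_id %||% ""),
                            character(1))),
    class = "reference_distribution")
}

# Reliability-weighted variance with the standard bias correction.
weighted_var <- function(x, w, xbar = sum(w * x) / sum(w)) {
  sum(w * (x - xbar)^2) / (sum(w) - sum(w^2) / sum(w))
}

#' Inter-study plausibility test for a control cohort
#'
#' Tests whether a new control cohort's fitted Weibull parameters are
#' consistent with the reference distribution of high-quality controls.
#' The statistic is the squared Mahalanobis distance
#' `d2 = (theta - mean)' cov^-1 (theta - mean)` of `theta = (lambda, rho)`
#' from the reference mean. Because the reference mean and covariance are
#' themselves estimated from `n` studies and the new cohort is a single
#' further observation, the default uses the one-new-observation Hotelling
#' form `T2 = d2 n/(n+1)`, referred to `T2 (n-p)/(p(n-1)) ~ F(p, n-p)` with
#' `p = 2`; a chi-squared(2) approximation is available via `method`.
#' The p-value is the plausibility score: a cohort with `p > alpha` is
#' recognized as plausible, otherwise as an outlier.
#'
#' @param new_fit A `weibull_fit` of the cohort under test (or any object
#'   with `lam` and `rho`).
#' @param ref A `reference_distribution` from [estimate_reference()].
#' @param alpha Significance level (default 0.01).
#' @param method `"hotelling_f"` (default) or `"chisq"`.
#' @return A `plausibility_result`: `d2`, `t2`, `p_value`, `alpha`,
#'   `verdict` (`plausible`/`outlier`), `method`.
#' @export
plausibility_test <- function(new_fit, ref, alpha = 0.01,
                              method = c("hotelling_f", "chisq")) {
  method <- match.arg(method)
  if (!inherits(ref, "reference_distribution")) {
    abort_validation("`ref` must be a reference_distribution")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort_validation("`alpha` must lie in (0, 1)")
  }
  theta <- c(new_fit$lam, new_fit$rho)
  if (any(!is.finite(theta)) || any(theta <= 0)) {
    abort_validation("new fit must carry positive finite lam and rho")
  }
  d2 <- tryCatch(
    stats::mahalanobis(theta, unname(ref$mean), ref$cov),
    error = function(e) abort_numerical(
      "singular reference covariance; re-estimate the reference with a ridge (see estimate_reference)"))
  n <- ref$n_studies; p <- 2
  t2 <- d2 * n / (n + 1)
  p_value <- if (method == "hotelling_f") {
    stats::pf(t2 * (n - p) / (p * (n - 1)), p, n - p, lower.tail = FALSE)
  } else {
    stats::pchisq(d2, df = p, lower.tail = FALSE)
  }
  structure(
    list(d2 = d2, t2 = t2, p_value = p_value, alpha = alpha,
         verdict = if (p_value <= alpha) "outlier" else "plausible",
         method = method, n_studies = n),
    class = "plausibility_result")
}

#' @export
print.reference_distribution <- function(x, ...) {
  cat(sprintf("<reference_distribution> %d studies\n", x$n_studies))
  cat(sprintf("  mean: lambda = %.4g d, rho = %.4g\n", x$mean[1], x$mean[2]))
  cat(sprintf("  cov : [%.4g, %.4g; %.4g, %.4g]\n",
              x$cov[1, 1], x$cov[1, 2], x$cov[2, 1], x$cov[2, 2]))
  invisible(x)
}

#' @export
print.plausibility_result <- function(x, ...) {
  cat(sprintf("<plausibility_result> %s (alpha = %g)\n", toupper(x$verdict),
              x$alpha))
  cat(sprintf("  Mahalanobis d2 = %.4g, T2 = %.4g, plausibility score P = %.4g\n",
              x$d2, x$t2, x$p_value))
  invisible(x)
}
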