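#' Maximal downward derivative of a survival curve
#'
#' The test statistic of the extra-mortality test: the largest drop rate of
#' the step-function survival estimate over consecutive grid intervals,
#' `max_k (S(t_{k-1}) - S(t_k)) / (t_k - t_{k-1})`, with `t_0 = 0` and
#' `S(0) = 1`. On a uniform grid this orders cohorts exactly like the bare
#' maximal vertical step; the derivative form also handles irregular check
#' schedules.
#'
#' @param curve A `survival_curve` from [kaplan_meier()].
#' @param grid Optional grid; defaults to the curve's own times.
#' @return The maximal drop rate, in 1/days (0 for a flat curve).
#' @export
max_survival_derivative <- function(curve, grid = curve$times) {
  if (length(grid) < 1L) abort_validation("grid must contain at least one step")
  s <- c(1, curve$survival)
  dt <- diff(c(0, grid))
  max((-diff(s)) / dt)
}

#' Intra-study extra-mortality test
#'
#' Flags an implausibly large single drop of the Kaplan-Meier survival curve
#' — the signature of a mass-death husbandry artifact — by comparing the
#' observed maximal drop rate with its null distribution under parametric
#' models fitted to the same cohort. For each model (Weibull and/or
#' Gompertz): the model is fitted to the data, `n_resamples` cohorts of the
#' same size are drawn from the fit, each resampled cohort is binned onto the
#' original measurement grid and its Kaplan-Meier maximal drop rate computed,
#' and the resampling p-value is `(1 + k)/(n_resamples + 1)` with `k` the
#' number of resampled statistics at least as large as the observed one
#' (ties count toward `k`).
#'
#' Resampled cohorts contain deaths only; censoring in the original cohort
#' enters through the parametric fit. A note is emitted when more than 10%
#' of the input is censored, since the null then ignores the censoring
#' pattern itself.
#'
#' @param dataset A [lifespan_dataset()] with at least two distinct death
#'   times.
#' @param models Character subset of `c("weibull", "gompertz")`.
#' @param n_resamples Number of model resamples per model (>= 100).
#' @param alpha Significance level in (0, 1); a model's verdict is `failed`
#'   when its p-value is `<= alpha`.
#' @param seed Optional integer seed (stored in the result).
#' @param overall `"all"` (default): the cohort fails overall only if it
#'   fails under every tested model — a single adequate model explains the
#'   largest drop. `"any"`: fail if any model rejects.
#' @return An `em_result`: `observed_stat` (1/days), `per_model` (p-value and
#'   resample summary per model), `n_resamples`, `alpha`, `verdict`
#'   (`passed`/`failed` overall), `verdict_per_model`, `seed`.
#' @examples
#' d <- generate_cohort(n = 50, lam = 900, rho = 6, seed = 7)
#' extra_mortality_test(d, n_resamples = 200, seed = 7)
#' @export
extra_mortality_test <- function(dataset, models = c("weibull", "gompertz"),
                                 n_resamples = 1000, alpha = 0.01,
                                 seed = NULL, overall = c("all", "any")) {
  validate_dataset(dataset)
  overall <- match.arg(overall)
  models <- match.arg(models, c("weibull", "gompertz"), several.ok = TRUE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort_validation("`alpha` must lie in (0, 1)")
  }
  if (!is.numeric(n_resamples) || n_resamples < 100) {
    abort_validation("`n_resamples` must be at least 100")
  }
  n_resamples <- as.integer(n_resamples)
  cens_frac <- mean(dataset$event == 0L)
  if (cens_frac > 0.10) {
    message(sprintf(
      "note: %.0f%% of records are censored; parametric resamples contain deaths only",
      100 * cens_frac))
  }

  km <- kaplan_meier(dataset)
  observed <- max_survival_derivative(km)
  n <- length(dataset$time)
  grid <- dataset$grid

  fits <- lapply(models, function(m) {
    tryCatch(
      switch(m, weibull = fit_weibull(dataset), gompertz = fit_gompertz(dataset)),
      lifespanqc_error = function(e) {
        abort_numerical("extra-mortality test: %s fit failed (%s)", m,
                        conditionMessage(e))
      })
  })
  names(fits) <- models

  per_model <- with_seed(seed, lapply(fits, function(fit) {
    stats_r <- resample_max_derivs(fit, n, grid, n_resamples)
    k <- sum(stats_r >= observed - 1e-12)
    p <- (1 + k) / (n_resamples + 1)
    list(p_value = p,
         resample_stats = c(min = min(stats_r), median = stats::median(stats_r),
                            q95 = unname(stats::quantile(stats_r, 0.95)),
                            max = max(stats_r)),
         n_exceeding = k)
  }))

  verdict_per_model <- vapply(per_model, function(m) {
    if (m$p_value <= alpha) "failed" else "passed"
  }, character(1))
  failed_overall <- if (overall == "all") all(verdict_per_model == "failed")
                    else any(verdict_per_model == "failed")

  structure(
    list(observed_stat = observed, per_model = per_model,
         n_resamples = n_resamples, alpha = alpha,
         verdict = if (failed_overall) "failed" else "passed",
         verdict_per_model = as.list(verdict_per_model),
         overall_rule = overall, models = models,
         fits = fits, seed = seed),
    class = "em_result")
}

# Vectorized null distribution of the max drop rate: draw n * n_resamples
# death times from the fit in one call, ceiling-bin them onto the grid
# (clamping past the last check, as bin_to_grid does), count deaths per
# (grid cell, resample) with a single tabulate, and take per-resample maxima
# of (d_k/n)/(t_k - t_{k-1}). With deaths only, the KM drop at a grid time
# is exactly d_k/n, so no product-limit recursion is needed.
resample_max_derivs <- function(fit, n, grid, n_resamples) {
  x <- sample_deaths(fit, n * n_resamples)
  K <- length(grid)
  idx <- findInterval(x, grid, left.open = TRUE) + 1L
  idx[idx > K] <- K
  col0 <- rep.int(seq_len(n_resamples) - 1L, rep.int(n, n_resamples))
  counts <- tabulate(idx + col0 * K, nbins = K * n_resamples)
  D <- matrix(counts / n, nrow = K) / diff(c(0, grid))
  Dt <- t(D)
  j <- max.col(Dt, ties.method = "first")
  Dt[cbind(seq_len(n_resamples), j)]
}

#' @export
print.em_result <- function(x, ...) {
  cat(sprintf("<em_result> extra-mortality test: %s (alpha = %g, %d resamples)\n",
              toupper(x$verdict), x$alpha, x$n_resamples))
  cat(sprintf("  observed max |dS/dt| = %.4g /day\n", x$observed_stat))
  for (m in names(x$per_model)) {
    cat(sprintf("  %-8s p = %.4g -> %s\n", m, x$per_model[[m]]$p_value,
                x$verdict_per_model[[m]]))
  }
  invisible(x)
}
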