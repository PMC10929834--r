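#' Generate a synthetic lifespan cohort
#'
#' Emulates a mouse lifespan experiment: death times are drawn from a
#' Weibull or Gompertz model, an optional fraction of animals is
#' right-censored at a uniform random time before their death, an optional
#' single-day mass-death "spike" reassigns a fraction of the observed deaths
#' to one day (total cohort size preserved — the signature artifact the
#' extra-mortality test targets), and all times are then binned onto a
#' regular measurement grid (checks every `grid_spacing` days, deaths found
#' at the first check after death).
#'
#' Defaults mirror a typical male C57BL/6J control cohort: Weibull scale 900
#' days and shape 6 (median about 847 days), weekly cage checks, no
#' censoring.
#'
#' @param n Cohort size (>= 2).
#' @param model `"weibull"` or `"gompertz"`.
#' @param lam,rho Weibull scale (days) and shape, used when
#'   `model = "weibull"`.
#' @param a,b Gompertz baseline hazard and rate (1/days), used when
#'   `model = "gompertz"`.
#' @param grid_spacing Days between checks (> 0; 1 = daily, 7 = weekly).
#' @param censor_fraction Fraction of animals right-censored, in [0, 1).
#' @param spike_time Day of the mass-death artifact (snapped to the grid),
#'   or `NULL` for none.
#' @param spike_fraction Fraction of the cohort killed at `spike_time`, in
#'   (0, 1); `ceiling(spike_fraction * n)` observed deaths are reassigned.
#' @param seed Optional integer seed; same seed, same cohort.
#' @param study_id Study identifier for the metadata.
#' @param group Metadata group label.
#' @return A validated [lifespan_dataset()].
#' @examples
#' d <- generate_cohort(n = 50, seed = 1)
#' kaplan_meier(d)
#' @export
generate_cohort <- function(n, model = c("weibull", "gompertz"),
                            lam = 900, rho = 6, a = 1e-5, b = 0.01,
                            grid_spacing = 7, censor_fraction = 0,
                            spike_time = NULL, spike_fraction = NULL,
                            seed = NULL, study_id = "sim", group = "control") {
  model <- match.arg(model)
  if (!is.numeric(n) || n < 2 || n != round(n)) {
    abort_validation("`n` must be an integer >= 2")
  }
  if (grid_spacing <= 0) abort_validation("`grid_spacing` must be positive")
  if (censor_fraction < 0 || censor_fraction >= 1) {
    abort_validation("`censor_fraction` must lie in [0, 1)")
  }
  if (!is.null(spike_time) != !is.null(spike_fraction)) {
    abort_validation("supply both `spike_time` and `spike_fraction`, or neither")
  }
  if (!is.null(spike_fraction) &&
      (spike_fraction <= 0 || spike_fraction >= 1)) {
    abort_validation("`spike_fraction` must lie in (0, 1)")
  }
  n <- as.integer(n)
  with_seed(seed, {
    death <- switch(model,
                    weibull = stats::rweibull(n, shape = rho, scale = lam),
                    gompertz = rgompertz_qc(n, a = a, b = b))
    time <- death
    event <- rep.int(1L, n)
    if (censor_fraction > 0) {
      idx <- sample.int(n, round(censor_fraction * n))
      time[idx] <- stats::runif(length(idx), 0, death[idx])
      event[idx] <- 0L
    }
    if (!is.null(spike_time)) {
      deaths_idx <- which(event == 1L)
      k <- min(ceiling(spike_fraction * n), length(deaths_idx))
      hit <- sample(deaths_idx, k)
      time[hit] <- spike_time
    }
    grid <- seq(grid_spacing, by = grid_spacing,
                length.out = ceiling(max(time) / grid_spacing))
    time <- bin_to_grid(time, grid)
    lifespan_dataset(time = time, event = event, grid = grid,
                     metadata = example_metadata(study_id, group = group))
  })
}

#' Generate a heterogeneous population of control studies
#'
#' Draws per-study Weibull parameters `(lambda_i, rho_i)` from a 2-D
#' Gaussian (rejection-truncated to the positive quadrant) — the generative
#' assumption behind the inter-study reference distribution — and generates
#' one cohort per study with [generate_cohort()]. The true drawn parameters
#' are recorded in each study's metadata (`true_lam`, `true_rho`) for
#' recovery checks.
#'
#' @param k_studies Number of studies (>= 1).
#' @param param_mean Length-2 vector: population mean of (lambda, rho).
#' @param param_cov 2x2 symmetric positive-semidefinite covariance of the
#'   study-level parameters.
#' @param n Animals per cohort.
#' @param grid_spacing,censor_fraction Passed to [generate_cohort()].
#' @param seed Optional integer seed.
#' @param study_prefix Prefix for generated study ids.
#' @return List of `k_studies` validated [lifespan_dataset()] objects.
#' @export
generate_population <- function(k_studies, param_mean = c(880, 6),
                                param_cov = diag(c(40^2, 0.5^2)),
                                n = 50, grid_spacing = 7, censor_fraction = 0,
                                seed = NULL, study_prefix = "study") {
  if (!is.numeric(k_studies) || k_studies < 1 || k_studies != round(k_studies)) {
    abort_validation("`k_studies` must be an integer >= 1")
  }
  param_cov <- as.matrix(param_cov)
  if (!isTRUE(all.equal(param_cov, t(param_cov))) ||
      any(eigen(param_cov, symmetric = TRUE, only.values = TRUE)$values < -1e-8)) {
    abort_validation("`param_cov` must be symmetric positive semidefinite")
  }
  with_seed(seed, {
    lapply(seq_len(k_studies), function(i) {
      par <- draw_positive_params(param_mean, param_cov)
      d <- generate_cohort(n = n, model = "weibull", lam = par[1], rho = par[2],
                           grid_spacing = grid_spacing,
                           censor_fraction = censor_fraction,
                           study_id = sprintf("%s%03d", study_prefix, i))
      d$metadata$true_lam <- par[1]
      d$metadata$true_rho <- par[2]
      d
    })
  })
}

draw_positive_params <- function(mean, cov) {
  for (i in 1:1000) {
    par <- as.numeric(MASS::mvrnorm(1, mu = mean, Sigma = cov))
    if (all(par > 0)) return(par)
  }
  abort_numerical("could not draw positive (lambda, rho) from the population Gaussian")
}
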