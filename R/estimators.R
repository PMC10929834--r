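#' Kaplan-Meier survival estimate on the measurement grid
#'
#' Product-limit estimate of the survival function from right-censored data,
#' evaluated at every measurement-grid time (including checks with no
#' deaths): `S(t) = prod over t_i <= t of (1 - d_i/n_i)`, where `d_i` deaths
#' occur among `n_i` animals at risk at check `t_i`. Animals censored at a
#' check are counted at risk at that check and leave the risk set afterwards
#' (the standard deaths-before-censorings tie convention).
#'
#' @param dataset A [lifespan_dataset()].
#' @return A `survival_curve`: list with `times`, `survival`, `n_at_risk`,
#'   `n_deaths`, `n_censored`, one entry per grid time.
#' @examples
#' d <- lifespan_dataset(c(1, 2, 4), c(1, 1, 1), example_metadata("km-demo"))
#' kaplan_meier(d)$survival   # 2/3, 1/3, 0
#' @export
kaplan_meier <- function(dataset) {
  validate_dataset(dataset)
  cnt <- grid_counts(dataset)
  haz <- ifelse(cnt$n_at_risk > 0, cnt$n_deaths / cnt$n_at_risk, 0)
  structure(
    list(times = cnt$times, survival = cumprod(1 - haz),
         n_at_risk = cnt$n_at_risk, n_deaths = cnt$n_deaths,
         n_censored = cnt$n_censored),
    class = "survival_curve")
}

#' Nelson-Aalen cumulative-hazard estimate on the measurement grid
#'
#' `H(t) = sum over t_i <= t of d_i/n_i`, with the same risk-set and tie
#' conventions as [kaplan_meier()].
#'
#' @inheritParams kaplan_meier
#' @return A `hazard_curve`: list with `times` and `cumulative_hazard`.
#' @export
nelson_aalen <- function(dataset) {
  validate_dataset(dataset)
  cnt <- grid_counts(dataset)
  haz <- ifelse(cnt$n_at_risk > 0, cnt$n_deaths / cnt$n_at_risk, 0)
  structure(list(times = cnt$times, cumulative_hazard = cumsum(haz)),
            class = "hazard_curve")
}

# Death/censor/at-risk counts at each grid time.
grid_counts <- function(dataset) {
  g <- dataset$grid
  idx <- vapply(dataset$time, function(t) which.min(abs(g - t)), integer(1))
  nd <- tabulate(idx[dataset$event == 1L], nbins = length(g))
  nc <- tabulate(idx[dataset$event == 0L], nbins = length(g))
  n <- length(dataset$time)
  at_risk <- n - c(0L, utils::head(cumsum(nd + nc), -1L))
  list(times = g, n_deaths = nd, n_censored = nc, n_at_risk = at_risk)
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> %d grid times on [%g, %g]; final S = %.4g\n",
              length(x$times), min(x$times), max(x$times),
              x$survival[length(x$survival)]))
  invisible(x)
}

#' @export
print.hazard_curve <- function(x, ...) {
  cat(sprintf("<hazard_curve> %d grid times; final H = %.4g\n",
              length(x$times), x$cumulative_hazard[length(x$times)]))
  invisible(x)
}

#' Export a survival curve as a data frame
#'
#' @param x A `survival_curve`.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return A data frame with columns `time_days`, `survival`, `n_at_risk`,
#'   `n_deaths`, `n_censored` (the CSV export layout).
#' @export
as.data.frame.survival_curve <- function(x, row.names = NULL, optional = FALSE,
                                         ...) {
  data.frame(time_days = x$times, survival = x$survival,
             n_at_risk = x$n_at_risk, n_deaths = x$n_deaths,
             n_censored = x$n_censored)
}

#' Bin event times onto a measurement grid
#'
#' A death that occurs between two checks is discovered at the next check, so
#' each time is replaced by the smallest grid value greater than or equal to
#' it. Times beyond the last check are clamped to the last grid value with a
#' warning.
#'
#' @param times Numeric vector of positive times (days).
#' @param grid Strictly increasing numeric vector of check times (days).
#' @return Numeric vector of grid values, same length as `times`.
#' @examples
#' bin_to_grid(c(3.2, 7, 7.1), grid = c(7, 14))  # 7 7 14
#' @export
bin_to_grid <- function(times, grid) {
  if (length(grid) < 1L || any(diff(grid) <= 0)) {
    abort_validation("grid must be non-empty and strictly increasing")
  }
  idx <- findInterval(times, grid, left.open = TRUE) + 1L
  over <- idx > length(grid)
  if (any(over)) {
    warning(sprintf("%d time(s) beyond the last check clamped to t = %g",
                    sum(over), grid[length(grid)]), call. = FALSE)
    idx[over] <- length(grid)
  }
  grid[idx]
}
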