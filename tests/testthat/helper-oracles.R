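# Independent brute-force oracles and dataset builders shared across tests.

make_dataset <- function(time, event, grid = NULL, study_id = "test") {
  lifespan_dataset(time = time, event = event, grid = grid,
                   metadata = example_metadata(study_id))
}

# Product-limit estimate computed literally from the definition: walk the
# distinct times in order, count deaths and the risk set by subsetting the
# raw records at each step. Censored animals count as at risk at their own
# time and drop out afterwards.
km_oracle <- function(time, event, grid) {
  s <- 1
  out <- numeric(length(grid))
  for (k in seq_along(grid)) {
    t <- grid[k]
    at_risk <- sum(time >= t - 1e-9)
    deaths <- sum(event == 1 & abs(time - t) < 1e-9)
    if (at_risk > 0) s <- s * (1 - deaths / at_risk)
    out[k] <- s
  }
  out
}

na_oracle <- function(time, event, grid) {
  h <- 0
  out <- numeric(length(grid))
  for (k in seq_along(grid)) {
    t <- grid[k]
    at_risk <- sum(time >= t - 1e-9)
    deaths <- sum(event == 1 & abs(time - t) < 1e-9)
    if (at_risk > 0) h <- h + deaths / at_risk
    out[k] <- h
  }
  out
}

# Random valid dataset for round-trip and property tests.
random_dataset <- function(seed) {
  set.seed(seed)
  n <- sample(3:40, 1)
  grid <- sort(sample(seq(7, 700, by = 7), sample(4:25, 1)))
  time <- sample(grid, n, replace = TRUE)
  event <- rbinom(n, 1, 0.8)
  if (!any(event == 1)) event[1] <- 1L
  make_dataset(time, event, grid = grid,
               study_id = sprintf("rand%03d", seed))
}

# Every death/censoring pattern over fixed small time vectors, for the
# exhaustive product-limit checks.
enumerate_patterns <- function(times) {
  n <- length(times)
  lapply(seq_len(2^n) - 1L, function(code) {
    as.integer(intToBits(code)[seq_len(n)])
  })
}
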