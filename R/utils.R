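`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state, so
#' seeded package operations do not perturb the global random stream. A `NULL`
#' seed evaluates the code under the current stream unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_validation("`seed` must be a single finite integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Error taxonomy: validation errors (bad inputs / bad files) vs numerical
# errors (non-convergence, singular matrices). The CLI maps them to distinct
# exit codes.
abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("lifespanqc_validation_error", "lifespanqc_error")))
}

abort_numerical <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("lifespanqc_numerical_error", "lifespanqc_error")))
}

# Full-precision numeric -> string for lossless CSV round trips.
num_chr <- function(x) {
  vapply(x, function(v) {
    if (is.finite(v) && v == round(v) && abs(v) <= .Machine$integer.max) {
      sprintf("%d", as.integer(v))
    } else {
      sprintf("%.17g", v)
    }
  }, character(1))
}

stopifnot_flag <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation("`%s` must be a single finite number", name)
  }
  x
}
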