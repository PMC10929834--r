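#' Construct a lifespan dataset
#'
#' The package's central container: one record per animal (time in days and a
#' death/censoring indicator), the experiment's measurement grid (the days on
#' which cages were checked and deaths recorded), and study metadata. Deaths
#' are only observed at checks, so every record time must lie on the grid.
#'
#' @param time Numeric vector of positive event times, in days.
#' @param event Integer vector, same length: 1 = death observed, 0 =
#'   right-censored.
#' @param metadata Named list of study metadata. Mandatory keys: `study_id`,
#'   `species`, `strain`, `sex` (one of `male`, `female`, `mixed`, `unknown`),
#'   `source`, `group` (`control` or `treatment`). Optional: `intervention`,
#'   `reference_id`, `time_unit` (always `"days"` after construction). Extra
#'   keys are preserved.
#' @param grid Measurement grid: strictly increasing positive times, in days.
#'   Defaults to the sorted distinct record times.
#' @param subject_id Optional character vector of animal identifiers; defaults
#'   to `s1, s2, ...`.
#' @return An object of class `lifespan_dataset`.
#' @examples
#' d <- lifespan_dataset(c(100, 200, 300), c(1, 1, 1),
#'                       metadata = example_metadata("demo"))
#' d
#' @export
lifespan_dataset <- function(time, event, metadata, grid = NULL,
                             subject_id = NULL) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (is.null(subject_id)) subject_id <- paste0("s", seq_along(time))
  if (is.null(grid)) grid <- sort(unique(time))
  metadata <- validate_metadata(metadata)
  x <- structure(
    list(metadata = metadata, time = time, event = event,
         subject_id = as.character(subject_id), grid = as.numeric(grid)),
    class = "lifespan_dataset")
  validate_dataset(x)
  x
}

#' @export
print.lifespan_dataset <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("<lifespan_dataset> %s: %s %s %s (%s)\n",
              m$study_id, m$species, m$strain, m$sex, m$group))
  cat(sprintf("  n = %d animals, %d deaths, %d censored\n",
              length(x$time), sum(x$event == 1L), sum(x$event == 0L)))
  cat(sprintf("  measurement grid: %d times on [%g, %g] days\n",
              length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

metadata_required <- c("study_id", "species", "strain", "sex", "source", "group")
metadata_optional <- c("intervention", "reference_id", "time_unit")

sex_levels <- c("male", "female", "mixed", "unknown")
group_levels <- c("control", "treatment")

validate_metadata <- function(metadata) {
  if (!is.list(metadata)) abort_validation("metadata must be a named list")
  missing <- setdiff(metadata_required, names(metadata))
  if (length(missing)) {
    abort_validation("missing mandatory metadata key(s): %s",
                     paste(missing, collapse = ", "))
  }
  if (!nzchar(metadata$study_id)) abort_validation("metadata key `study_id` must be non-empty")
  if (!metadata$sex %in% sex_levels) {
    abort_validation("metadata key `sex` must be one of: %s (got '%s')",
                     paste(sex_levels, collapse = ", "), metadata$sex)
  }
  if (!metadata$group %in% group_levels) {
    abort_validation("metadata key `group` must be one of: %s (got '%s')",
                     paste(group_levels, collapse = ", "), metadata$group)
  }
  metadata$intervention <- metadata$intervention %||% ""
  metadata$reference_id <- metadata$reference_id %||% ""
  metadata$time_unit <- "days"
  metadata
}

#' Validate a lifespan dataset
#'
#' Checks the container invariants: positive times, binary events, a strictly
#' increasing grid, at least one record, and every record time on the grid.
#' Called by every operation that consumes a dataset.
#'
#' @param x A `lifespan_dataset`.
#' @return `x`, invisibly, or a validation error.
#' @export
validate_dataset <- function(x) {
  if (!inherits(x, "lifespan_dataset")) abort_validation("not a lifespan_dataset")
  n <- length(x$time)
  if (n < 1L) abort_validation("dataset must contain at least one record")
  if (length(x$event) != n || length(x$subject_id) != n) {
    abort_validation("time, event and subject_id must have equal length")
  }
  if (any(!is.finite(x$time)) || any(x$time <= 0)) {
    abort_validation("all record times must be positive finite numbers (days)")
  }
  if (!all(x$event %in% c(0L, 1L))) {
    abort_validation("event codes must be 0 (censored) or 1 (death)")
  }
  g <- x$grid
  if (length(g) < 1L || any(!is.finite(g)) || any(g <= 0) ||
      any(diff(g) <= 0)) {
    abort_validation("measurement grid must be strictly increasing positive times")
  }
  on_grid <- vapply(x$time, function(t) any(abs(g - t) < 1e-8), logical(1))
  if (!all(on_grid)) {
    abort_validation("record time(s) not on the measurement grid: %s",
                     paste(utils::head(x$time[!on_grid], 5), collapse = ", "))
  }
  validate_metadata(x$metadata)
  invisible(x)
}

#' Minimal metadata for examples and simulations
#'
#' @param study_id Study identifier.
#' @param group `"control"` or `"treatment"`.
#' @param ... Further metadata keys overriding the defaults.
#' @return A metadata list suitable for [lifespan_dataset()].
#' @export
example_metadata <- function(study_id, group = "control", ...) {
  out <- list(study_id = study_id, species = "Mus musculus",
              strain = "C57BL/6J", sex = "male", source = "simulated colony",
              group = group, intervention = "", reference_id = "",
              time_unit = "days")
  extra <- list(...)
  out[names(extra)] <- extra
  out
}
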