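#' Read a lifespan dataset from a plain-text file
#'
#' The file format is a metadata header of `#key=value` lines followed by a
#' CSV body (UTF-8, comma separator, `.` decimal). Two body layouts are
#' supported:
#'
#' * `long` — one row per animal, columns `subject_id,time_days,event`
#'   (event 1 = death, 0 = right-censored);
#' * `counts` — one row per measurement time, columns
#'   `time_days,n_deaths,n_censored`, expanded to per-animal records on read.
#'
#' Mandatory header keys are `study_id`, `species`, `strain`, `sex`, `source`
#' and `group`. An optional `#measurement_grid=` key lists the check times
#' (comma-separated, days); when absent, the grid is inferred as the sorted
#' distinct record times. A `#time_unit=weeks` or `months` header converts
#' all times to days on read (x7 and x30.44 respectively) with a warning;
#' the canonical unit is always days.
#'
#' @param path Path to the file.
#' @param format `"long"` or `"counts"`.
#' @return A validated [lifespan_dataset()].
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(path, format = c("long", "counts")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_validation("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_hdr <- grepl("^#", lines)
  # header block must be a leading run of #-lines
  hdr_lines <- lines[cumprod(is_hdr) == 1]
  body_lines <- lines[cumprod(is_hdr) != 1]
  if (!length(hdr_lines)) abort_validation("missing metadata header block in %s", path)

  meta <- parse_header(hdr_lines, path)
  unit <- tolower(meta$time_unit %||% "days")
  scale <- switch(unit, days = 1, weeks = 7, months = 30.44,
                  abort_validation("unknown time_unit '%s' in %s", unit, path))
  if (scale != 1) {
    warning(sprintf("converting times from %s to days (x%g) in %s",
                    unit, scale, path), call. = FALSE)
  }
  grid <- NULL
  if (!is.null(meta$measurement_grid)) {
    grid <- as.numeric(strsplit(meta$measurement_grid, ",")[[1]]) * scale
    meta$measurement_grid <- NULL
  }
  meta$time_unit <- "days"

  body <- parse_body(body_lines, format, offset = length(hdr_lines), path = path)
  lifespan_dataset(time = body$time * scale, event = body$event,
                   metadata = meta, grid = grid, subject_id = body$subject_id)
}

parse_header <- function(hdr_lines, path) {
  kv <- sub("^#", "", hdr_lines)
  kv <- kv[nzchar(trimws(kv))]
  m <- regmatches(kv, regexec("^([^=]+)=(.*)$", kv))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    abort_validation("malformed header line(s) in %s: %s", path,
                     paste(kv[bad], collapse = "; "))
  }
  meta <- stats::setNames(lapply(m, function(x) trimws(x[3])),
                          trimws(vapply(m, `[`, character(1), 2)))
  missing <- setdiff(metadata_required, names(meta))
  if (length(missing)) {
    abort_validation("missing mandatory metadata key(s) in %s: %s",
                     path, paste(missing, collapse = ", "))
  }
  meta
}

parse_body <- function(body_lines, format, offset, path) {
  body_lines <- body_lines[nzchar(trimws(body_lines))]
  if (length(body_lines) < 2L) {
    abort_validation("no data rows in %s", path)
  }
  df <- utils::read.csv(text = body_lines, stringsAsFactors = FALSE,
                        colClasses = "character")
  needed <- switch(format,
                   long = c("subject_id", "time_days", "event"),
                   counts = c("time_days", "n_deaths", "n_censored"))
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort_validation("%s body lacks column(s): %s", format,
                     paste(missing, collapse = ", "))
  }
  # line numbers in the original file: header + column-name row + data rows
  lineno <- offset + 1L + seq_len(nrow(df))
  num <- function(col, kind = c("positive", "count")) {
    kind <- match.arg(kind)
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- !is.finite(v)
    bad <- bad | if (kind == "positive") v <= 0 else (v < 0 | v != round(v))
    bad[is.na(bad)] <- TRUE
    if (any(bad)) {
      abort_validation("invalid value in column `%s` at line %d of %s: '%s'",
                       col, lineno[which(bad)[1]], path, df[[col]][which(bad)[1]])
    }
    v
  }
  if (format == "long") {
    time <- num("time_days")
    ev <- suppressWarnings(as.numeric(df$event))
    bad <- !is.finite(ev) | !(ev %in% c(0, 1))
    if (any(bad)) {
      abort_validation("unknown event code at line %d of %s: '%s' (expected 0 or 1)",
                       lineno[which(bad)[1]], path, df$event[which(bad)[1]])
    }
    list(subject_id = df$subject_id, time = time, event = as.integer(ev))
  } else {
    time <- num("time_days")
    nd <- num("n_deaths", kind = "count")
    nc <- num("n_censored", kind = "count")
    if (any(nd + nc == 0)) {
      abort_validation("counts row with zero animals at line %d of %s",
                       lineno[which(nd + nc == 0)[1]], path)
    }
    time_out <- rep.int(time, nd + nc)
    event_out <- unlist(lapply(seq_along(time), function(i) {
      rep.int(c(1L, 0L), c(nd[i], nc[i]))
    }), use.names = FALSE)
    list(subject_id = paste0("s", seq_along(time_out)),
         time = time_out, event = as.integer(event_out))
  }
}

#' Write a lifespan dataset to a plain-text file
#'
#' Inverse of [read_dataset()]: emits the `#key=value` metadata header
#' (including the full measurement grid, so check times with no recorded
#' deaths survive the round trip) followed by the CSV body in the requested
#' layout. `read_dataset(write_dataset(d))` reproduces `d` exactly in `long`
#' format, and up to subject-id relabelling in `counts` format (counts rows
#' carry no per-animal identifiers).
#'
#' @param dataset A valid [lifespan_dataset()].
#' @param path Output path.
#' @param format `"long"` or `"counts"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, format = c("long", "counts")) {
  format <- match.arg(format)
  validate_dataset(dataset)
  meta <- dataset$metadata
  meta$measurement_grid <- paste(num_chr(dataset$grid), collapse = ",")
  hdr <- sprintf("#%s=%s", names(meta), vapply(meta, as.character, character(1)))
  if (format == "long") {
    body <- c("subject_id,time_days,event",
              sprintf("%s,%s,%d", dataset$subject_id, num_chr(dataset$time),
                      dataset$event))
  } else {
    tt <- sort(unique(dataset$time))
    nd <- vapply(tt, function(t) sum(dataset$event == 1L & dataset$time == t),
                 integer(1))
    nc <- vapply(tt, function(t) sum(dataset$event == 0L & dataset$time == t),
                 integer(1))
    body <- c("time_days,n_deaths,n_censored",
              sprintf("%s,%d,%d", num_chr(tt), nd, nc))
  }
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) abort_validation("cannot write to %s: %s",
                                                       path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Serialize a result object to JSON
#'
#' Writes fits, test results, meta-controls and reference distributions as
#' JSON with stable key names, embedding the package version. Matrices are
#' written as row-major nested arrays.
#'
#' @param x A `weibull_fit`, `gompertz_fit`, `em_result`, `meta_control`,
#'   `reference_distribution`, `plausibility_result` or `treatment_effect`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  lst <- as_result_list(x)
  lst$lifespanqc_version <- as.character(utils::packageVersion("lifespanqc"))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

as_result_list <- function(x) {
  type <- class(x)[1]
  strip <- function(v) {
    if (is.list(v)) lapply(unclass(v), strip) else v
  }
  c(list(object = type), strip(unclass(x)))
}

#' Read a Weibull fit, meta-control or reference distribution back from JSON
#'
#' Restores objects written by [write_result_json()] far enough to be reused
#' downstream (e.g. a reference distribution for [plausibility_test()], or a
#' meta-control for [treatment_effect()]).
#'
#' @param path Path to a JSON file produced by [write_result_json()].
#' @return The restored object.
#' @export
read_result_json <- function(path) {
  if (!file.exists(path)) abort_validation("file not found: %s", path)
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  type <- lst$object %||% abort_validation("%s is not a lifespanqc result file", path)
  lst$object <- NULL
  lst$lifespanqc_version <- NULL
  for (k in c("cov", "param_cov")) {
    if (!is.null(lst[[k]])) lst[[k]] <- matrix(unlist(lst[[k]]), 2, 2, byrow = TRUE)
  }
  if (!is.null(lst$mean)) lst$mean <- as.numeric(unlist(lst$mean))
  if (!is.null(lst$component_fits) && is.data.frame(lst$component_fits)) {
    lst$component_fits <- lapply(seq_len(nrow(lst$component_fits)), function(i) {
      as.list(lst$component_fits[i, ])
    })
  }
  structure(lst, class = type)
}
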