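#' Read a beat-to-beat RR-interval file
#'
#' Two plain-text dialects are accepted:
#' \itemize{
#'   \item one interval in milliseconds per line, `#` starting a comment;
#'   \item a 2-column CSV with header `time_s, rr_ms` (only `rr_ms` is
#'     used; beat times are rebuilt from the cumulative intervals).
#' }
#' Malformed or non-physiological values are reported with their line
#' number.
#'
#' @param path File path.
#' @return An [ibi_series()].
#' @export
read_rr <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  header_csv <- length(lines) > 0 && grepl("rr_ms", lines[1], fixed = TRUE)
  if (header_csv) {
    d <- utils::read.csv(path)
    if (!("rr_ms" %in% names(d))) stop("CSV lacks rr_ms column", call. = FALSE)
    vals <- d$rr_ms
    line_no <- seq_along(vals) + 1
  } else {
    stripped <- sub("#.*$", "", lines)
    keep <- which(trimws(stripped) != "")
    if (!length(keep)) stop("no beats", call. = FALSE)
    vals <- suppressWarnings(as.numeric(trimws(stripped[keep])))
    line_no <- keep
  }
  bad <- which(is.na(vals) | vals <= 0 | vals >= 5000)
  if (length(bad)) {
    stop(sprintf("invalid RR interval at line %d of %s", line_no[bad[1]], path),
         call. = FALSE)
  }
  ibi_series(vals)
}

#' Read phase markers from a JSON sidecar
#'
#' The sidecar holds the six keys `rest_start_s`, `rest_end_s`,
#' `squat_start_s`, `squat_end_s`, `recovery_start_s`, `recovery_end_s`
#' (seconds from the start of the recording).
#'
#' @param path Path to the JSON file.
#' @return A [phase_markers()].
#' @export
read_phases <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("rest_start_s", "rest_end_s", "squat_start_s", "squat_end_s",
           "recovery_start_s", "recovery_end_s")
  missing <- setdiff(req, names(cfg))
  if (length(missing)) stop(sprintf("phase sidecar lacks key(s): %s",
                                    paste(missing, collapse = ", ")), call. = FALSE)
  do.call(phase_markers, cfg[req])
}

#' Write / read a cleaned heart-rate series as CSV
#'
#' Columns `time_s`, `hr_bpm`, `phase` (comma-separated, `.` decimal,
#' header mandatory). `read_hr_csv` rebuilds the phase markers from the
#' label column when present.
#'
#' @param hr An [hr_series()].
#' @param path File path.
#' @return `write_hr_csv` returns `path` invisibly; `read_hr_csv` an
#'   [hr_series()].
#' @export
write_hr_csv <- function(hr, path) {
  utils::write.csv(as.data.frame(hr), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hr_csv
#' @export
read_hr_csv <- function(path) {
  d <- utils::read.csv(path)
  req <- c("time_s", "hr_bpm")
  missing <- setdiff(req, names(d))
  if (length(missing)) stop(sprintf("HR CSV lacks column(s): %s",
                                    paste(missing, collapse = ", ")), call. = FALSE)
  phases <- NULL
  if ("phase" %in% names(d) && any(d$phase != "")) {
    span <- function(lab) range(d$time_s[d$phase == lab])
    r <- span("rest"); s <- span("squat"); v <- span("recovery")
    phases <- phase_markers(r[1], r[2] + 1, s[1], s[2] + 1, v[1], v[2])
  }
  hr_series(d$time_s, d$hr_bpm, phases)
}

#' Read a subject metadata CSV
#'
#' Requires columns `subject_id`, `sex` (1 male / 0 female), `age` (years),
#' `height` (m), `weight` (kg); `vo2max_measured` (L/min) is optional.
#' Rows violating the plausibility bounds (age 10-100, height 1.2-2.3 m,
#' weight 30-200 kg) are rejected.
#'
#' @param path File path.
#' @return Data frame of subjects.
#' @export
read_subjects <- function(path) {
  d <- utils::read.csv(path)
  req <- c("subject_id", "sex", "age", "height", "weight")
  missing <- setdiff(req, names(d))
  if (length(missing)) stop(sprintf("subject CSV lacks column(s): %s",
                                    paste(missing, collapse = ", ")), call. = FALSE)
  if (!all(d$sex %in% c(0, 1))) stop("sex must be coded 1 (male) / 0 (female)",
                                     call. = FALSE)
  bad <- d$age <= 10 | d$age >= 100 | d$height <= 1.2 | d$height >= 2.3 |
    d$weight <= 30 | d$weight >= 200
  if (any(bad)) stop(sprintf("implausible subject row(s): %s",
                             paste(d$subject_id[bad], collapse = ", ")), call. = FALSE)
  d
}

#' Read a norms table CSV
#'
#' Columns `sex`, `age_low`, `age_high`, `poor_below_ml_kg_min`,
#' `good_at_or_above_ml_kg_min`; validated by [norms_table()].
#'
#' @param path File path.
#' @return A [norms_table()].
#' @export
read_norms_csv <- function(path) {
  norms_table(utils::read.csv(path))
}

#' Serialise / load a model spec as a flat key = coefficient text file
#'
#' One `term = value` pair per line.
#'
#' @param model A [vo2_model()].
#' @param path File path.
#' @return `write_model_spec` returns `path` invisibly; `read_model_spec`
#'   a [vo2_model()].
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "vo2_model"))
  co <- model$coefficients
  writeLines(sprintf("%s = %.17g", names(co), co), path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  parts <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop("malformed model spec file", call. = FALSE)
  co <- vapply(parts, function(p) as.numeric(trimws(p[2])), numeric(1))
  names(co) <- vapply(parts, function(p) trimws(p[1]), character(1))
  vo2_model(co)
}
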