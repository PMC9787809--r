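gaze_columns <- c("subject", "trial", "t_s", "x_deg", "y_deg", "torsion_deg",
                  "head_tilt_nominal_deg", "head_tilt_measured_deg",
                  "image_tilt_deg", "image_type")

#' Read and write the gaze-sample CSV dialect
#'
#' One row per eye-tracker sample, UTF-8, header row, `.` decimal
#' separator; columns `subject, trial, t_s, x_deg, y_deg, torsion_deg,
#' head_tilt_nominal_deg, head_tilt_measured_deg, image_tilt_deg,
#' image_type`. `torsion_deg` may be empty (`NA`) throughout.
#'
#' @param path CSV file path.
#' @param gaze gaze-sample data frame (for writing).
#' @return `read_gaze_csv()` returns the data frame; `write_gaze_csv()`
#'   returns `path` invisibly.
#' @export
read_gaze_csv <- function(path) {
  if (!file.exists(path)) stop("gaze file not found: ", path)
  g <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(setdiff(gaze_columns, "torsion_deg"), names(g))
  if (length(miss) > 0)
    stop("gaze CSV missing columns: ", paste(miss, collapse = ", "))
  if (is.null(g$torsion_deg)) g$torsion_deg <- NA_real_
  g
}

#' @rdname read_gaze_csv
#' @export
write_gaze_csv <- function(gaze, path) {
  cols <- intersect(gaze_columns, names(gaze))
  write.csv(gaze[, cols, drop = FALSE], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write the saccade-table CSV dialect
#'
#' One row per detected saccade: `subject, trial, onset_t, offset_t,
#' duration_ms, amplitude_deg, peak_vel_dps, direction_deg` plus the
#' trial's condition columns.
#'
#' @param path CSV file path.
#' @param saccades saccade table (for writing).
#' @return `read_saccades_csv()` returns the data frame;
#'   `write_saccades_csv()` returns `path` invisibly.
#' @export
read_saccades_csv <- function(path) {
  if (!file.exists(path)) stop("saccade file not found: ", path)
  s <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("subject", "direction_deg"), names(s))
  if (length(miss) > 0)
    stop("saccade CSV missing columns: ", paste(miss, collapse = ", "))
  s
}

#' @rdname read_saccades_csv
#' @export
write_saccades_csv <- function(saccades, path) {
  write.csv(saccades, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a gaze-sample table or CSV file
#'
#' Schema and sanity report: missing or extra columns, non-numeric
#' values, non-monotone timestamps within a trial, and condition-cell
#' coverage per subject. A missing torsion column is a warning-level
#' issue (torsion analyses are skipped), not an error.
#'
#' @param x a gaze data frame or a CSV path.
#' @return an object of class `gaze_validation`: list with `issues`
#'   (data frame: `severity`, `what`), `coverage` (trials per subject x
#'   head tilt x image tilt x image type), and `ok` (no error-level
#'   issues).
#' @export
validate_input <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("unreadable file: ", x)
    x <- read.csv(x, stringsAsFactors = FALSE)
  }
  issues <- data.frame(severity = character(0), what = character(0))
  note <- function(severity, what) {
    issues <<- rbind(issues, data.frame(severity = severity, what = what))
  }
  required <- setdiff(gaze_columns, "torsion_deg")
  for (cn in setdiff(required, names(x))) note("error", paste("missing column:", cn))
  if (!"torsion_deg" %in% names(x))
    note("warning", "missing column: torsion_deg (torsion analyses skipped)")
  for (cn in setdiff(names(x), gaze_columns)) note("warning", paste("extra column:", cn))
  num_cols <- intersect(setdiff(gaze_columns, "image_type"), names(x))
  for (cn in num_cols) {
    if (!is.numeric(x[[cn]])) note("error", paste("non-numeric column:", cn))
  }
  coverage <- NULL
  if (all(c("subject", "trial", "t_s") %in% names(x)) && is.numeric(x$t_s)) {
    key <- paste(x$subject, x$trial, sep = "\r")
    bad <- vapply(split(x$t_s, key), function(t) any(diff(t) <= 0), TRUE)
    for (k in names(bad)[bad])
      note("error", paste("non-monotone timestamps in subject/trial",
                          gsub("\r", "/", k)))
    if (all(c("head_tilt_nominal_deg", "image_tilt_deg", "image_type")
            %in% names(x))) {
      first <- x[!duplicated(key), , drop = FALSE]
      coverage <- as.data.frame(table(
        subject = first$subject, head_tilt = first$head_tilt_nominal_deg,
        image_tilt = first$image_tilt_deg, image_type = first$image_type))
      names(coverage)[5] <- "n_trials"
    }
  }
  structure(list(issues = issues, coverage = coverage,
                 ok = !any(issues$severity == "error")),
            class = "gaze_validation")
}

#' @export
print.gaze_validation <- function(x, ...) {
  if (nrow(x$issues) == 0) {
    cat("Gaze table valid: no issues.\n")
  } else {
    cat("Gaze table validation:", sum(x$issues$severity == "error"), "error(s),",
        sum(x$issues$severity == "warning"), "warning(s)\n")
    for (i in seq_len(nrow(x$issues)))
      cat(sprintf("  [%s] %s\n", x$issues$severity[i], x$issues$what[i]))
  }
  invisible(x)
}
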