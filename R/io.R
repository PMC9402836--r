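read_csv_strict <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs)) {
    lines <- sprintf("line %d, column %d: expected %s, got %s",
                     probs$row, probs$col, probs$expected, probs$actual)
    abort(paste0("Parse error in ", path, ":\n  ",
                 paste(head(lines, 10), collapse = "\n  ")))
  }
  out
}

#' Read and write the pipeline's CSV schemas
#'
#' All files are UTF-8 comma-separated with a header row, `.` as decimal
#' separator, booleans as `true`/`false` (case-insensitive on read, written
#' upper-case by [readr::write_csv()]), enum values as lower-snake-case
#' tokens and empty cells for missing optional values.
#'
#' * Assessment CSV: one row per patient, columns named as in
#'   [assessment_fields()], optional `patient_id`.
#' * Outcome CSV: `patient_id`, `score_class` (low/high), `care_setting`
#'   (gp/cardiologist), `hf_admission`, `cardiac_admission`, `death`.
#' * Rater CSV (long format): `subject_id`, `rater_id`, `total`.
#'
#' @param path CSV file path.
#' @param lenient Passed to [validate_assessments()].
#' @return A validated tibble in the corresponding schema.
#' @export
read_assessments <- function(path, lenient = FALSE) {
  validate_assessments(read_csv_strict(path), lenient = lenient)
}

#' @rdname read_assessments
#' @export
read_outcomes <- function(path) {
  validate_outcome_records(read_csv_strict(path))
}

#' @rdname read_assessments
#' @param thresholds Threshold record used to derive the stable/unstable
#'   class from each total.
#' @export
read_rater_pairs <- function(path, thresholds = mishf_thresholds()) {
  long <- read_csv_strict(path)
  need <- c("subject_id", "rater_id", "total")
  missing_cols <- setdiff(need, names(long))
  if (length(missing_cols)) {
    abort(paste0("Rater CSV lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  totals <- suppressWarnings(as.numeric(long$total))
  if (anyNA(totals)) {
    bad <- which(is.na(totals))
    abort(paste0("Rater CSV has non-numeric totals at data row(s): ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  long$total <- totals
  counts <- table(long$subject_id)
  if (any(counts != 2)) {
    abort(paste0("Every subject needs exactly two ratings; offending subject(s): ",
                 paste(head(names(counts)[counts != 2], 10), collapse = ", ")))
  }
  long |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::arrange(.data$rater_id, .by_group = TRUE) |>
    dplyr::summarise(rater1_total = .data$total[1],
                     rater2_total = .data$total[2], .groups = "drop") |>
    dplyr::mutate(
      rater1_class = ifelse(.data$rater1_total <= thresholds$stable_max, "stable", "unstable"),
      rater2_class = ifelse(.data$rater2_total <= thresholds$stable_max, "stable", "unstable"))
}

#' @rdname read_assessments
#' @param x Tibble to write.
#' @export
write_csv_output <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' A small machine-readable record written next to command outputs: command
#' name, input and output paths, a digest of the effective configuration
#' (the digest changes exactly when the effective configuration changes),
#' the seed, the package version and a timestamp.
#'
#' @param command Command name.
#' @param inputs,outputs Character vectors of paths.
#' @param config The effective configuration (any list).
#' @param seed Integer seed or `NA`.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(command, inputs, outputs, config, seed = NA_integer_) {
  structure(list(
    command = command,
    inputs = as.character(inputs),
    outputs = as.character(outputs),
    config_digest = config_digest(config),
    seed = seed,
    tool_version = as.character(utils::packageVersion("mishf")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path Output path for the JSON file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
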