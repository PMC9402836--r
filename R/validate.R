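mishf_enums <- list(
  dyspnoea_status    = c("none_or_improved", "worse_on_exercise", "orthopnoea_or_new_nocturnal"),
  rhythm             = c("sinus", "atrial_fibrillation", "other_irregular"),
  weight_status      = c("stable", "increased_gt2kg_1week", "decreased", "decreased_with_cachexia"),
  angina_status      = c("none_or_stable_ccs_le2", "progressive", "ccs_class3"),
  anaemia_chronicity = c("new", "chronic")
)

required_fields <- c(
  "nyha_class", "dyspnoea_status", "systolic_bp", "diastolic_bp",
  "hypotension_symptoms", "rhythm", "heart_rate", "rhythm_new_onset",
  "rhythm_symptomatic", "weight_status", "oedema_present", "angina_status",
  "uptitration_incomplete", "poor_compliance_suspected", "poor_social_support",
  "depression_signs", "hf_admissions_last_6mo", "hf_admissions_last_12mo"
)

optional_fields <- c(
  "ntprobnp_current", "ntprobnp_previous", "potassium", "sodium",
  "creatinine_current", "creatinine_previous", "gfr", "haemoglobin",
  "anaemia_chronicity"
)

flag_fields <- c(
  "hypotension_symptoms", "rhythm_new_onset", "rhythm_symptomatic",
  "oedema_present", "uptitration_incomplete", "poor_compliance_suspected",
  "poor_social_support", "depression_signs"
)

#' Validate a table of patient assessments
#'
#' Checks the schema (all required columns present) and every row against the
#' clinical invariants of the instrument: NYHA class in 1--4, enum fields
#' restricted to their tokens, physiological quantities non-negative,
#' diastolic below systolic pressure, and the 6-month admission count not
#' exceeding the 12-month count. Optional laboratory fields may be missing
#' independently; required fields may not. An angina description beyond CCS
#' class 3 (tokens `ccs_class4` or `unstable`) is rejected explicitly: such
#' patients are outside the instrument's remit and need specialist care
#' directly.
#'
#' @param data A data frame, one row per patient, columns named as in
#'   the assessment schema (see [mishf_items()] and the package vignette).
#' @param lenient If `FALSE` (default) any problem aborts with a message
#'   naming the offending rows and fields. If `TRUE`, offending rows are
#'   dropped and returned problems are attached as attribute `"problems"`.
#' @return The validated tibble (invisibly typed: enums as character,
#'   flags as logical, counts as integer), with a `patient_id` column added
#'   when absent.
#' @export
validate_assessments <- function(data, lenient = FALSE) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(required_fields, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (f in setdiff(optional_fields, names(data))) data[[f]] <- NA
  if (!"patient_id" %in% names(data)) {
    data$patient_id <- if (nrow(data)) paste0("P", seq_len(nrow(data))) else character()
  }

  data <- coerce_assessment_types(data)
  problems <- assessment_problems(data)

  if (nrow(problems) && !lenient) {
    msg <- problems |>
      dplyr::mutate(line = sprintf("row %d, %s: %s", .data$row, .data$field, .data$message)) |>
      dplyr::pull("line")
    abort(paste0("Invalid assessment record(s):\n  ",
                 paste(head(msg, 20), collapse = "\n  "),
                 if (nrow(problems) > 20) sprintf("\n  ... and %d more", nrow(problems) - 20) else ""))
  }
  if (nrow(problems)) {
    data <- data[-unique(problems$row), , drop = FALSE]
  }
  attr(data, "problems") <- problems
  data
}

coerce_assessment_types <- function(data) {
  num_fields <- c("systolic_bp", "diastolic_bp", "heart_rate",
                  "ntprobnp_current", "ntprobnp_previous", "potassium", "sodium",
                  "creatinine_current", "creatinine_previous", "gfr", "haemoglobin")
  for (f in num_fields) data[[f]] <- as.numeric(data[[f]])
  for (f in c("nyha_class", "hf_admissions_last_6mo", "hf_admissions_last_12mo")) {
    data[[f]] <- as.integer(data[[f]])
  }
  for (f in flag_fields) data[[f]] <- as.logical(data[[f]])
  for (f in names(mishf_enums)) data[[f]] <- as.character(data[[f]])
  data
}

assessment_problems <- function(data) {
  probs <- list()
  note <- function(bad, field, message) {
    bad <- which(!is.na(bad) & bad)
    if (length(bad)) {
      probs[[length(probs) + 1]] <<- tibble::tibble(row = bad, field = field, message = message)
    }
  }

  note(!data$nyha_class %in% 1:4 | is.na(data$nyha_class),
       "nyha_class", "must be an integer in 1-4")

  for (f in names(mishf_enums)) {
    v <- data[[f]]
    allowed <- mishf_enums[[f]]
    optional <- f %in% optional_fields
    if (f == "angina_status") {
      note(v %in% c("ccs_class4", "unstable"), f,
           "CCS class 4 / unstable angina is outside the instrument; refer to specialist care directly")
    }
    bad <- !is.na(v) & !v %in% allowed
    if (!optional) bad <- bad | is.na(v)
    note(bad, f, paste0("must be one of: ", paste(allowed, collapse = ", ")))
  }

  for (f in c("systolic_bp", "diastolic_bp", "heart_rate")) {
    note(is.na(data[[f]]) | data[[f]] < 0, f, "must be a non-negative number")
  }
  for (f in c("ntprobnp_current", "ntprobnp_previous", "potassium", "sodium",
              "creatinine_current", "creatinine_previous", "gfr", "haemoglobin")) {
    note(!is.na(data[[f]]) & data[[f]] < 0, f, "must be non-negative when present")
  }
  note(data$diastolic_bp >= data$systolic_bp, "diastolic_bp",
       "diastolic pressure must be below systolic pressure")

  for (f in flag_fields) note(is.na(data[[f]]), f, "must be true or false")

  for (f in c("hf_admissions_last_6mo", "hf_admissions_last_12mo")) {
    note(is.na(data[[f]]) | data[[f]] < 0, f, "must be a non-negative count")
  }
  note(data$hf_admissions_last_6mo > data$hf_admissions_last_12mo,
       "hf_admissions_last_6mo", "cannot exceed the 12-month admission count")

  note(duplicated(data$patient_id) | is.na(data$patient_id), "patient_id",
       "must be present and unique")

  if (!length(probs)) {
    return(tibble::tibble(row = integer(), field = character(), message = character()))
  }
  dplyr::arrange(dplyr::bind_rows(probs), .data$row, .data$field)
}
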