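#' Evaluate the MIS-HF items for a table of patients
#'
#' Applies every item of the instrument's scoring list to each row of
#' `data` and returns one record per patient and item. Items whose required
#' inputs are absent (the laboratory items, when those values were not
#' collected) are returned with `assessed = FALSE` and zero points, never as
#' an error: the instrument was designed for routine practice where
#' laboratory values are drawn only when clinically indicated.
#'
#' Item logic, with the default cut-offs of [mishf_thresholds()]:
#' * NYHA class: III scores 1, IV scores 3.
#' * Dyspnoea: worse on exercise 1; new orthopnoea or nocturnal dyspnoea 3.
#' * Blood pressure: below 90/50 mm Hg (both limbs) with symptoms 1;
#'   above 140 systolic or 85 diastolic 1.
#' * Heart rate/rhythm: sinus above 75/min 2; atrial fibrillation above
#'   100/min 2; a new irregular rhythm 2; a symptomatic irregular rhythm 2.
#'   The rate, new-onset and symptomatic items add.
#' * Weight: gain above 2 kg in a week 1; loss 1; loss with cachexia 2.
#' * Oedema present 1.
#' * Angina: progressive 3; CCS class 3 2.
#' * NT-proBNP: rise above 25% versus the previous value 1, and level above
#'   400 pmol/l 1 -- two independent items that may both fire.
#' * Potassium outside 3.5--5.0 mmol/l 1; sodium outside 135--145 mmol/l 1.
#' * Creatinine above 220 umol/l, or risen above 25%, or GFR below
#'   30 ml/min: 1 point, fired at most once however many sub-criteria hold.
#' * Haemoglobin below 6.5 mmol/l: 2 if the anaemia is new, 1 if chronic
#'   (chronic is assumed when the chronicity is not recorded).
#' * One point each: incomplete up-titration, suspected poor compliance,
#'   poor social support, signs of depression.
#' * Heart-failure admissions: at least one in 6 months or two in 12
#'   months, 2 points.
#'
#' @param data Assessment table; validated with [validate_assessments()].
#' @param thresholds A [mishf_thresholds()] record.
#' @param validate Set to `FALSE` only when `data` has already been
#'   validated (used internally to avoid re-validation).
#' @return A tibble with columns `patient_id`, `item_id`, `points`, `fired`,
#'   `assessed`, `detail`, ordered as the item catalogue, 22 rows per patient.
#' @seealso [mishf_score()] for per-patient totals and classification.
#' @export
score_items <- function(data, thresholds = mishf_thresholds(), validate = TRUE) {
  stopifnot(inherits(thresholds, "mishf_thresholds"))
  if (validate) data <- validate_assessments(data)
  blocks <- evaluate_item_blocks(data, thresholds)
  long <- dplyr::bind_rows(blocks)
  # blocks are patient-ordered within item; reorder patient-major, items in
  # catalogue order within each patient (order() is stable)
  long[order(rep(seq_len(nrow(data)), length(blocks))), , drop = FALSE]
}

evaluate_item_blocks <- function(data, thresholds) {
  th <- thresholds
  n <- nrow(data)

  item <- function(item_id, points, fired, assessed = TRUE, detail = "") {
    assessed <- rep_len(assessed, n)
    fired <- rep_len(fired, n) & assessed
    tibble::tibble(
      patient_id = data$patient_id,
      item_id = item_id,
      points = as.integer(ifelse(fired, rep_len(points, n), 0L)),
      fired = fired,
      assessed = assessed,
      detail = ifelse(fired, rep_len(detail, n),
                      ifelse(assessed, "", "required input missing"))
    )
  }

  out <- list()

  out$nyha <- item("nyha", ifelse(data$nyha_class == 4L, 3L, 1L),
                   data$nyha_class >= 3L, detail = "NYHA class III/IV")

  dys <- data$dyspnoea_status
  out$dyspnoea <- item("dyspnoea",
                       ifelse(dys == "orthopnoea_or_new_nocturnal", 3L, 1L),
                       dys != "none_or_improved", detail = "dyspnoea worse or new orthopnoea")

  out$bp_hypotension <- item(
    "bp_hypotension", 1L,
    data$systolic_bp < th$bp_low_systolic & data$diastolic_bp < th$bp_low_diastolic &
      data$hypotension_symptoms,
    detail = "symptomatic hypotension")
  out$bp_hypertension <- item(
    "bp_hypertension", 1L,
    data$systolic_bp > th$bp_high_systolic | data$diastolic_bp > th$bp_high_diastolic,
    detail = "blood pressure above limit")

  out$hr_sinus <- item("hr_sinus", 2L,
                       data$rhythm == "sinus" & data$heart_rate > th$sinus_rate_high,
                       detail = "sinus tachycardia")
  out$hr_af <- item("hr_af", 2L,
                    data$rhythm == "atrial_fibrillation" & data$heart_rate > th$af_rate_high,
                    detail = "rapid atrial fibrillation")
  irregular <- data$rhythm != "sinus"
  out$rhythm_new <- item("rhythm_new", 2L, irregular & data$rhythm_new_onset,
                         detail = "new irregular rhythm")
  out$rhythm_symptomatic <- item("rhythm_symptomatic", 2L,
                                 irregular & data$rhythm_symptomatic,
                                 detail = "symptomatic irregular rhythm")

  wt <- data$weight_status
  out$weight <- item("weight", ifelse(wt == "decreased_with_cachexia", 2L, 1L),
                     wt != "stable", detail = "weight change")

  out$oedema <- item("oedema", 1L, data$oedema_present, detail = "oedema present")

  ang <- data$angina_status
  out$angina <- item("angina", ifelse(ang == "progressive", 3L, 2L),
                     ang != "none_or_stable_ccs_le2", detail = "angina progressive/class 3")

  has_bnp <- !is.na(data$ntprobnp_current)
  has_bnp_prev <- has_bnp & !is.na(data$ntprobnp_previous) & data$ntprobnp_previous > 0
  rise <- ifelse(has_bnp_prev,
                 (data$ntprobnp_current - data$ntprobnp_previous) / data$ntprobnp_previous * 100,
                 NA_real_)
  out$ntprobnp_rise <- item("ntprobnp_rise", 1L,
                            !is.na(rise) & rise > th$ntprobnp_rise_pct,
                            assessed = has_bnp_prev, detail = "NT-proBNP rise > 25%")
  out$ntprobnp_level <- item("ntprobnp_level", 1L,
                             has_bnp & data$ntprobnp_current > th$ntprobnp_high,
                             assessed = has_bnp, detail = "NT-proBNP above 400 pmol/l")

  has_k <- !is.na(data$potassium)
  out$potassium <- item("potassium", 1L,
                        has_k & (data$potassium < th$potassium_low | data$potassium > th$potassium_high),
                        assessed = has_k, detail = "potassium out of range")
  has_na <- !is.na(data$sodium)
  out$sodium <- item("sodium", 1L,
                     has_na & (data$sodium < th$sodium_low | data$sodium > th$sodium_high),
                     assessed = has_na, detail = "sodium out of range")

  has_cr <- !is.na(data$creatinine_current)
  has_cr_prev <- has_cr & !is.na(data$creatinine_previous) & data$creatinine_previous > 0
  has_gfr <- !is.na(data$gfr)
  cr_high <- has_cr & data$creatinine_current > th$creatinine_high
  cr_rise <- has_cr_prev &
    (data$creatinine_current - data$creatinine_previous) / data$creatinine_previous * 100 >
      th$creatinine_rise_pct
  gfr_low <- has_gfr & data$gfr < th$gfr_low
  out$creatinine <- item("creatinine", 1L, cr_high | cr_rise | gfr_low,
                         assessed = has_cr | has_gfr,
                         detail = "renal function criterion met")

  has_hb <- !is.na(data$haemoglobin)
  anaemic <- has_hb & data$haemoglobin < th$haemoglobin_low
  hb_new <- !is.na(data$anaemia_chronicity) & data$anaemia_chronicity == "new"
  out$haemoglobin <- item("haemoglobin", ifelse(anaemic & hb_new, 2L, 1L),
                          anaemic, assessed = has_hb,
                          detail = "anaemia (new 2 / chronic 1)")

  out$uptitration <- item("uptitration", 1L, data$uptitration_incomplete,
                          detail = "up-titration incomplete")
  out$compliance <- item("compliance", 1L, data$poor_compliance_suspected,
                         detail = "poor compliance suspected")
  out$social_support <- item("social_support", 1L, data$poor_social_support,
                             detail = "poor social support")
  out$depression <- item("depression", 1L, data$depression_signs,
                         detail = "signs of depression")

  out$hf_admission <- item(
    "hf_admission", 2L,
    data$hf_admissions_last_6mo >= th$admissions_6mo_min |
      data$hf_admissions_last_12mo >= th$admissions_12mo_min,
    detail = "recent HF admission history")

  out[mishf_items()$item_id]
}

#' Score patients with the MIS-HF and classify stability
#'
#' Evaluates all items ([score_items()]), sums the points per patient and
#' applies the referral threshold: a total of 0, 1 or 2 is a stable clinical
#' condition and maps to a primary-care recommendation; 3 or more indicates
#' clinical instability and maps to specialist care. `completeness` is the
#' fraction of items that could be assessed; `underestimation_flag` is raised
#' when a laboratory item was unassessed and the total is still in the stable
#' range, because missing laboratory values can only hide points (a falsely
#' low score), never add them.
#'
#' @inheritParams score_items
#' @return A tibble, one row per patient: `patient_id`, one integer points
#'   column per item (named by `item_id`), `total`, `completeness`,
#'   `stability_class` (`"stable"`/`"unstable"`), `recommendation`
#'   (`"primary_care"`/`"specialist_care"`), `underestimation_flag`.
#' @examples
#' pat <- generate_cohort(cohort_config(n_patients = 5, seed = 42))
#' mishf_score(pat[c("patient_id", assessment_fields())])
#' @export
mishf_score <- function(data, thresholds = mishf_thresholds(), validate = TRUE) {
  if (validate) data <- validate_assessments(data)
  if (nrow(data) == 0) return(empty_score_result())
  n <- nrow(data)
  items <- mishf_items()
  blocks <- evaluate_item_blocks(data, thresholds)

  pts <- matrix(unlist(lapply(blocks, function(b) b$points), use.names = FALSE), nrow = n)
  assessed <- matrix(unlist(lapply(blocks, function(b) b$assessed), use.names = FALSE), nrow = n)
  colnames(pts) <- colnames(assessed) <- items$item_id

  total <- as.integer(rowSums(pts))
  lab_unassessed <- rowSums(!assessed[, items$is_lab, drop = FALSE]) > 0
  stable <- total <= thresholds$stable_max

  dplyr::bind_cols(
    tibble::tibble(patient_id = data$patient_id),
    tibble::as_tibble(pts),
    tibble::tibble(
      total = total,
      completeness = rowMeans(assessed),
      stability_class = ifelse(stable, "stable", "unstable"),
      recommendation = ifelse(stable, "primary_care", "specialist_care"),
      underestimation_flag = lab_unassessed & stable
    )
  )
}

empty_score_result <- function() {
  item_cols <- stats::setNames(
    rep(list(integer()), nrow(mishf_items())), mishf_items()$item_id)
  tibble::tibble(
    patient_id = character(), !!!item_cols,
    total = integer(), completeness = double(),
    stability_class = character(), recommendation = character(),
    underestimation_flag = logical()
  )
}

#' Names of the assessment schema columns
#'
#' @return Character vector of all input field names (required then optional).
#' @export
assessment_fields <- function() c(required_fields, optional_fields)
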