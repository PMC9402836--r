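# A fully normal assessment: every item quiet, every lab collected.
normal_assessment <- function(n = 1) {
  tibble::tibble(
    patient_id = paste0("P", seq_len(n)),
    nyha_class = 1L,
    dyspnoea_status = "none_or_improved",
    systolic_bp = 120, diastolic_bp = 80,
    hypotension_symptoms = FALSE,
    rhythm = "sinus", heart_rate = 70,
    rhythm_new_onset = FALSE, rhythm_symptomatic = FALSE,
    weight_status = "stable", oedema_present = FALSE,
    angina_status = "none_or_stable_ccs_le2",
    ntprobnp_current = 200, ntprobnp_previous = 200,
    potassium = 4.2, sodium = 140,
    creatinine_current = 90, creatinine_previous = 90,
    gfr = 70, haemoglobin = 8.5, anaemia_chronicity = NA_character_,
    uptitration_incomplete = FALSE, poor_compliance_suspected = FALSE,
    poor_social_support = FALSE, depression_signs = FALSE,
    hf_admissions_last_6mo = 0L, hf_admissions_last_12mo = 0L
  )
}

# The normal assessment with named fields overridden.
assessment_with <- function(...) {
  a <- normal_assessment()
  mods <- list(...)
  for (f in names(mods)) a[[f]] <- mods[[f]]
  a
}

# Points of one item for a single modified assessment.
item_points <- function(item, ...) {
  long <- score_items(assessment_with(...))
  long$points[long$item_id == item]
}

# The four published outcome strata rebuilt from their printed counts
# (group size, HF admissions, cardiac admissions, deaths, composite).
published_outcome_records <- function() {
  dplyr::bind_rows(
    outcome_records_from_counts(205, 11, 3, 13, 20, "low", "gp"),
    outcome_records_from_counts(124, 11, 2, 6, 16, "low", "cardiologist"),
    outcome_records_from_counts(41, 4, 0, 7, 9, "high", "gp"),
    outcome_records_from_counts(267, 51, 6, 48, 81, "high", "cardiologist")
  )
}

# Exact binomial 99% acceptance band for an observed count.
within_binom99 <- function(count, n, p) {
  count >= stats::qbinom(0.005, n, p) && count <= stats::qbinom(0.995, n, p)
}
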