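#' The MIS-HF item catalogue
#'
#' One row per scored item group of the instrument. Graded alternatives that
#' the questionnaire lists as rows of one clinical dimension (the four NYHA
#' classes, the three dyspnoea states, the weight states, the angina states,
#' new versus chronic anaemia) collapse into a single item whose points
#' depend on the level, so the catalogue has 22 scored items covering all 33
#' questionnaire rows. `exclusive_group` marks items that cannot fire
#' together for physiological reasons (a blood pressure is not both
#' hypotensive and hypertensive; a rhythm is either sinus or not), which
#' bounds the maximum reachable total.
#'
#' @return A tibble with columns `item_id`, `label`, `max_points`,
#'   `is_lab` (items that depend on laboratory values and may be unassessed
#'   when those values were not collected) and `exclusive_group`.
#' @examples
#' mishf_items()
#' @export
mishf_items <- function() {
  tibble::tribble(
    ~item_id,             ~label,                                              ~max_points, ~is_lab, ~exclusive_group,
    "nyha",               "NYHA functional class III/IV",                      3L, FALSE, "nyha",
    "dyspnoea",           "Worsening dyspnoea / new orthopnoea",               3L, FALSE, "dyspnoea",
    "bp_hypotension",     "BP < 90/50 mm Hg with symptoms of hypotension",     1L, FALSE, "blood_pressure",
    "bp_hypertension",    "BP > 140/85 mm Hg",                                 1L, FALSE, "blood_pressure",
    "hr_sinus",           "Sinus rhythm > 75 beats/min",                       2L, FALSE, "heart_rate",
    "hr_af",              "Atrial fibrillation > 100 beats/min",               2L, FALSE, "heart_rate",
    "rhythm_new",         "Irregular rhythm / AF (new)",                       2L, FALSE, "rhythm_new",
    "rhythm_symptomatic", "Irregular rhythm / AF with symptoms",               2L, FALSE, "rhythm_symptomatic",
    "weight",             "Weight increased > 2 kg/week, decreased, cachexia", 2L, FALSE, "weight",
    "oedema",             "Oedema present",                                    1L, FALSE, "oedema",
    "angina",             "Angina pectoris progressive / CCS class 3",         3L, FALSE, "angina",
    "ntprobnp_rise",      "NT-proBNP increased > 25%",                         1L, TRUE,  "ntprobnp_rise",
    "ntprobnp_level",     "NT-proBNP > 400 pmol/l",                            1L, TRUE,  "ntprobnp_level",
    "potassium",          "Potassium < 3.5 or > 5.0 mmol/l",                   1L, TRUE,  "potassium",
    "sodium",             "Sodium < 135 or > 145 mmol/l",                      1L, TRUE,  "sodium",
    "creatinine",         "Creatinine > 220 umol/l, rise > 25%, GFR < 30",     1L, TRUE,  "creatinine",
    "haemoglobin",        "Haemoglobin < 6.5 mmol/l (new 2 / chronic 1)",      2L, TRUE,  "haemoglobin",
    "uptitration",        "Up-titration to maximum tolerated dose not achieved", 1L, FALSE, "uptitration",
    "compliance",         "Poor compliance with therapy (suspected)",          1L, FALSE, "compliance",
    "social_support",     "Poor social support",                               1L, FALSE, "social_support",
    "depression",         "Signs of depression",                               1L, FALSE, "depression",
    "hf_admission",       "HF admission (>= 1 in 6 months or >= 2 in 1 year)", 2L, FALSE, "hf_admission"
  )
}

#' Maximum reachable MIS-HF total
#'
#' The largest total a single assessment can produce under the instrument's
#' mutual-exclusivity structure: within each exclusive group only the
#' highest-scoring alternative can fire, and groups add.
#'
#' @param thresholds A [mishf_thresholds()] record (the cut-offs do not
#'   change the per-item points, but the record is accepted so callers can
#'   hold one configuration object).
#' @param items The item catalogue; defaults to [mishf_items()]. Supplying a
#'   reduced or re-grouped catalogue bounds the corresponding rule set.
#' @return A single integer.
#' @examples
#' max_possible_score() # 32 under the default rules
#' @export
max_possible_score <- function(thresholds = mishf_thresholds(), items = mishf_items()) {
  stopifnot(inherits(thresholds, "mishf_thresholds"))
  per_group <- tapply(items$max_points, items$exclusive_group, max)
  as.integer(sum(per_group))
}
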