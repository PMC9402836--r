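#' Stratified effect estimates over an outcome table
#'
#' Reproduces the analysis layout of the instrument's validation study from
#' patient-level outcome records: within each score class, primary care (GP)
#' versus cardiologist 2x2 odds ratios per endpoint; plus the pooled
#' high-score versus low-score comparison over all patients. The composite
#' endpoint is the union of the three component events. Zero-cell tables
#' yield undefined estimates (reported, not corrected).
#'
#' @param outcomes Data frame with columns `score_class` (`"low"`/`"high"`),
#'   `care_setting` (`"gp"`/`"cardiologist"`) and logical `hf_admission`,
#'   `cardiac_admission`, `death` (a `composite` column is recomputed).
#' @param alpha_level Two-sided level for the Woolf intervals.
#' @return A tibble, one row per comparison x endpoint, with the columns of
#'   [odds_ratio_estimate()] plus `comparison` and `endpoint`.
#' @examples
#' rec <- dplyr::bind_rows(
#'   outcome_records_from_counts(205, 11, 3, 13, 20, "low", "gp"),
#'   outcome_records_from_counts(124, 11, 2, 6, 16, "low", "cardiologist"),
#'   outcome_records_from_counts(41, 4, 0, 7, 9, "high", "gp"),
#'   outcome_records_from_counts(267, 51, 6, 48, 81, "high", "cardiologist"))
#' analyze_outcomes(rec)
#' @export
analyze_outcomes <- function(outcomes, alpha_level = 0.05) {
  outcomes <- validate_outcome_records(outcomes)
  endpoints <- c("hf_admission", "cardiac_admission", "death", "composite")

  strata <- list(
    low_gp_vs_cardiologist = dplyr::filter(outcomes, .data$score_class == "low"),
    high_gp_vs_cardiologist = dplyr::filter(outcomes, .data$score_class == "high")
  )

  rows <- list()
  for (nm in names(strata)) {
    d <- strata[[nm]]
    if (length(unique(d$care_setting)) < 2) {
      abort(paste0("Stratum '", nm, "' does not contain both care settings"))
    }
    for (ep in endpoints) {
      ct <- contingency_2x2(
        sum(d[[ep]][d$care_setting == "gp"]), sum(d$care_setting == "gp"),
        sum(d[[ep]][d$care_setting == "cardiologist"]), sum(d$care_setting == "cardiologist"),
        labels = c("gp", "cardiologist"))
      rows[[paste(nm, ep)]] <- dplyr::mutate(
        odds_ratio_estimate(ct, alpha_level),
        comparison = nm, endpoint = ep, .before = 1)
    }
  }

  if (length(unique(outcomes$score_class)) < 2) {
    abort("Both score classes are required for the pooled high-vs-low comparison")
  }
  for (ep in endpoints) {
    ct <- contingency_2x2(
      sum(outcomes[[ep]][outcomes$score_class == "high"]), sum(outcomes$score_class == "high"),
      sum(outcomes[[ep]][outcomes$score_class == "low"]), sum(outcomes$score_class == "low"),
      labels = c("high", "low"))
    rows[[paste("high_vs_low", ep)]] <- dplyr::mutate(
      odds_ratio_estimate(ct, alpha_level),
      comparison = "high_vs_low", endpoint = ep, .before = 1)
  }
  dplyr::bind_rows(rows)
}

validate_outcome_records <- function(outcomes) {
  stopifnot(is.data.frame(outcomes))
  outcomes <- tibble::as_tibble(outcomes)
  need <- c("score_class", "care_setting", "hf_admission", "cardiac_admission", "death")
  missing_cols <- setdiff(need, names(outcomes))
  if (length(missing_cols)) {
    abort(paste0("Outcome records lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  bad_class <- setdiff(unique(outcomes$score_class), c("low", "high"))
  if (length(bad_class)) {
    abort(paste0("Unknown score_class token(s): ", paste(bad_class, collapse = ", ")))
  }
  bad_setting <- setdiff(unique(outcomes$care_setting), c("gp", "cardiologist"))
  if (length(bad_setting)) {
    abort(paste0("Unknown care_setting token(s): ", paste(bad_setting, collapse = ", ")))
  }
  for (ep in c("hf_admission", "cardiac_admission", "death")) {
    v <- as.logical(outcomes[[ep]])
    if (any(is.na(v))) abort(paste0("Column ", ep, " must be true/false"))
    outcomes[[ep]] <- v
  }
  outcomes$composite <- outcomes$hf_admission | outcomes$cardiac_admission | outcomes$death
  outcomes
}

#' Render an analysis report as aligned text
#'
#' Formats the output of [analyze_outcomes()] the way published outcome
#' tables print: `OR (low-high)` to two decimals, with an en-dash style
#' placeholder (`-`) where no odds ratio could be calculated because of a
#' zero cell.
#'
#' @param report Tibble from [analyze_outcomes()].
#' @return Character vector of report lines.
#' @export
format_analysis <- function(report) {
  fmt <- function(i) {
    r <- report[i, ]
    est <- if (isTRUE(r$estimate_defined)) {
      sprintf("%.2f (%.2f-%.2f) p=%.2f", r$odds_ratio, r$ci_low, r$ci_high, r$p_value)
    } else "-"
    sprintf("%-24s %-18s %3d/%-4d vs %3d/%-4d  OR %s",
            r$comparison, r$endpoint,
            r$events_g1, r$n_g1, r$events_g2, r$n_g2, est)
  }
  vapply(seq_len(nrow(report)), fmt, character(1))
}
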