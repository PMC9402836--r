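#' Configuration of the synthetic cohort generator
#'
#' Bundles every parameter of the synthetic heart-failure outpatient cohort:
#' per-item firing probabilities (calibrated once so that about 52% of
#' patients score in the stable range, the fraction observed in the
#' instrument's 637-patient validation cohort), referral adherence (62% of
#' stable patients referred to primary care, 14% of unstable patients), the
#' class-conditional 1-year event probabilities (composite 10.9% in the
#' stable class and 29.2% in the unstable class, with heart-failure
#' admission / cardiac admission / death component rates matching the
#' published per-class proportions), covariate distributions for adjustment
#' testing, and the score noise of a simulated second rater.
#'
#' Component events are generated as a correlated union: a shared standard
#' normal frailty per patient with loading `rho` solved numerically so the
#' union probability equals the configured composite rate (the published
#' component counts do not add up to the composite, so the components must
#' overlap).
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed; fixed seed gives fully reproducible output.
#' @param item_prevalences Named probabilities that each scored item fires
#'   (rhythm-dependent items are conditional on an eligible rhythm).
#' @param level_splits Conditional level probabilities within graded items.
#' @param lab_missingness Named probabilities that each laboratory field was
#'   not collected (labs are drawn only when clinically indicated, so
#'   missingness is a feature of real use, not an artefact).
#' @param rhythm_mix Probabilities of sinus rhythm, atrial fibrillation and
#'   other irregular rhythm.
#' @param low_to_gp_prob,high_to_gp_prob Probability that a stable / an
#'   unstable patient is referred to primary care.
#' @param event_rates Class-conditional composite and component event
#'   probabilities at 1 year; see [default_event_rates()].
#' @param covariates Age mean/sd, male fraction, COPD and diabetes
#'   prevalences used for the adjustment covariates.
#' @param rater_disagreement_sd Standard deviation of the integer score
#'   noise added for the simulated second rater.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 637,
                          seed = 1L,
                          item_prevalences = default_item_prevalences(),
                          level_splits = default_level_splits(),
                          lab_missingness = default_lab_missingness(),
                          rhythm_mix = c(sinus = 0.65, atrial_fibrillation = 0.30,
                                         other_irregular = 0.05),
                          low_to_gp_prob = 0.62,
                          high_to_gp_prob = 0.14,
                          event_rates = default_event_rates(),
                          covariates = default_covariate_model(),
                          rater_disagreement_sd = 1.2) {
  cfg <- structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    item_prevalences = item_prevalences, level_splits = level_splits,
    lab_missingness = lab_missingness, rhythm_mix = rhythm_mix,
    low_to_gp_prob = low_to_gp_prob, high_to_gp_prob = high_to_gp_prob,
    event_rates = event_rates, covariates = covariates,
    rater_disagreement_sd = rater_disagreement_sd
  ), class = "cohort_config")
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @export
default_item_prevalences <- function() {
  # Calibrated by scripts/tune_prevalences.R so ~52% of patients total <= 2.
  c(nyha = 0.2074, dyspnoea = 0.1382, bp_hypotension = 0.0207,
    bp_hypertension = 0.1382, hr_sinus = 0.1728, hr_af = 0.1728,
    rhythm_new = 0.0691, rhythm_symptomatic = 0.0691, weight = 0.1037,
    oedema = 0.1728, angina = 0.0346, ntprobnp_rise = 0.1382,
    ntprobnp_level = 0.2419, potassium = 0.0691, sodium = 0.0691,
    creatinine = 0.1382, haemoglobin = 0.1037, uptitration = 0.2074,
    compliance = 0.0691, social_support = 0.0691, depression = 0.0691,
    hf_admission = 0.1037)
}

#' @rdname cohort_config
#' @export
default_level_splits <- function() {
  list(nyha4_given_fired = 0.25, nyha2_given_quiet = 0.65,
       dyspnoea_orthopnoea = 0.25,
       weight = c(increased_gt2kg_1week = 0.5, decreased = 0.3,
                  decreased_with_cachexia = 0.2),
       angina_progressive = 0.5, anaemia_new = 0.4)
}

#' @rdname cohort_config
#' @export
default_lab_missingness <- function() {
  c(ntprobnp_current = 0.25, ntprobnp_previous = 0.35, potassium = 0.20,
    sodium = 0.20, creatinine_current = 0.20, creatinine_previous = 0.35,
    gfr = 0.25, haemoglobin = 0.20, anaemia_chronicity = 0.30)
}

#' @rdname cohort_config
#' @export
default_event_rates <- function() {
  list(
    low = list(composite = 36 / 329,
               components = c(hf_admission = 22 / 329,
                              cardiac_admission = 5 / 329,
                              death = 19 / 329)),
    high = list(composite = 90 / 308,
                components = c(hf_admission = 55 / 308,
                               cardiac_admission = 6 / 308,
                               death = 55 / 308))
  )
}

#' @rdname cohort_config
#' @export
default_covariate_model <- function() {
  list(age_mean = 74.3, age_sd = 12.0, male_fraction = 0.573,
       copd_prevalence = 0.25, diabetes_prevalence = 0.30)
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_patients < 1) abort("`n_patients` must be at least 1")
  probs <- c(cfg$item_prevalences, cfg$lab_missingness, cfg$rhythm_mix,
             low_to_gp = cfg$low_to_gp_prob, high_to_gp = cfg$high_to_gp_prob)
  bad <- probs < 0 | probs > 1 | !is.finite(probs)
  if (any(bad)) {
    abort(paste0("Probabilities must lie in [0, 1]; offending: ",
                 paste(names(probs)[bad], collapse = ", ")))
  }
  missing_items <- setdiff(names(default_item_prevalences()), names(cfg$item_prevalences))
  if (length(missing_items)) {
    abort(paste0("item_prevalences is missing: ", paste(missing_items, collapse = ", ")))
  }
  if (abs(sum(cfg$rhythm_mix) - 1) > 1e-8) abort("rhythm_mix must sum to 1")
  if (cfg$item_prevalences[["bp_hypotension"]] + cfg$item_prevalences[["bp_hypertension"]] > 1) {
    abort("bp_hypotension + bp_hypertension prevalences cannot exceed 1")
  }
  for (cls in c("low", "high")) {
    er <- cfg$event_rates[[cls]]
    if (any(er$components > er$composite + 1e-12)) {
      abort(paste0("Component event rates exceed the composite rate in class '", cls, "'"))
    }
    if (sum(er$components) < er$composite - 1e-12) {
      abort(paste0("Component rates sum below the composite rate in class '", cls,
                   "': the union cannot reach it"))
    }
  }
  if (!is.numeric(cfg$rater_disagreement_sd) || cfg$rater_disagreement_sd < 0) {
    abort("`rater_disagreement_sd` must be non-negative")
  }
  cfg
}

# Shared-frailty loading such that P(any component) equals the composite
# rate. Component j fires iff rho*L + sqrt(1-rho^2)*E_j < qnorm(p_j) with a
# common L, so the union probability falls from the independent union
# (rho = 0) to max(p_j) (rho -> 1).
solve_event_rho <- function(components, composite) {
  p <- components[components > 0]
  if (!length(p)) return(0)
  cuts <- qnorm(p)
  union_prob <- function(rho) {
    if (rho < 1e-12) return(1 - prod(1 - p))
    s <- sqrt(1 - rho^2)
    f <- function(l) {
      vapply(l, function(li) prod(pnorm((cuts - rho * li) / s, lower.tail = FALSE)), double(1)) *
        stats::dnorm(l)
    }
    1 - integrate(f, -8, 8, rel.tol = 1e-10)$value
  }
  indep <- union_prob(0)
  if (composite > indep + 1e-9) {
    abort("Composite rate exceeds the union of independent components")
  }
  if (composite < max(p) - 1e-9) {
    abort("Composite rate is below the largest component rate")
  }
  if (abs(composite - indep) < 1e-9) return(0)
  uniroot(function(r) union_prob(r) - composite, c(0, 0.999), tol = 1e-9)$root
}

#' Generate a synthetic heart-failure outpatient cohort
#'
#' Samples per-item firing indicators from the configured prevalences,
#' realises clinical field values consistent with each firing pattern (a
#' patient whose potassium item fires receives an out-of-range potassium,
#' and so on), blanks laboratory fields according to the configured
#' missingness, scores every patient with the real scoring engine
#' ([mishf_score()]; never a shortcut), assigns the care setting by score
#' class with the configured adherence probabilities, and draws 1-year
#' outcomes from the class-conditional event model (correlated components
#' whose union matches the configured composite rate). Fully reproducible
#' under a fixed `seed`.
#'
#' @param cfg A [cohort_config()].
#' @return A tibble, one row per patient: `patient_id`, every assessment
#'   field, covariates (`age`, `sex`, `copd`, `diabetes`), the score results
#'   (`total`, `completeness`, `stability_class`, `recommendation`,
#'   `underestimation_flag`, `score_class` as `"low"`/`"high"`),
#'   `care_setting` (`"gp"`/`"cardiologist"`) and the outcome flags
#'   (`hf_admission`, `cardiac_admission`, `death`, `composite`). The
#'   configuration is attached as attribute `"config"`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 200, seed = 7))
#' table(cohort$score_class, cohort$care_setting)
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  validate_cohort_config(cfg)
  withr::with_seed(cfg$seed, generate_cohort_impl(cfg))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_patients
  prev <- cfg$item_prevalences
  sp <- cfg$level_splits
  bern <- function(p) runif(n) < p

  # --- per-item firing indicators -------------------------------------------
  f_nyha <- bern(prev[["nyha"]])
  f_dysp <- bern(prev[["dyspnoea"]])
  u_bp <- runif(n) # hypo / hyper mutually exclusive
  f_hypo <- u_bp < prev[["bp_hypotension"]]
  f_hyper <- !f_hypo & u_bp < prev[["bp_hypotension"]] + prev[["bp_hypertension"]]
  rhythm <- sample(names(cfg$rhythm_mix), n, replace = TRUE, prob = cfg$rhythm_mix)
  f_sinus_t <- rhythm == "sinus" & bern(prev[["hr_sinus"]])
  f_af_t <- rhythm == "atrial_fibrillation" & bern(prev[["hr_af"]])
  f_new <- rhythm != "sinus" & bern(prev[["rhythm_new"]])
  f_sympt <- rhythm != "sinus" & bern(prev[["rhythm_symptomatic"]])
  f_weight <- bern(prev[["weight"]])
  f_oedema <- bern(prev[["oedema"]])
  f_angina <- bern(prev[["angina"]])
  f_bnp_rise <- bern(prev[["ntprobnp_rise"]])
  f_bnp_level <- bern(prev[["ntprobnp_level"]])
  f_pot <- bern(prev[["potassium"]])
  f_sod <- bern(prev[["sodium"]])
  f_crea <- bern(prev[["creatinine"]])
  f_hb <- bern(prev[["haemoglobin"]])
  f_adm <- bern(prev[["hf_admission"]])

  # --- realise clinical fields consistent with the firing pattern ----------
  nyha <- ifelse(f_nyha,
                 ifelse(bern(sp$nyha4_given_fired), 4L, 3L),
                 ifelse(bern(sp$nyha2_given_quiet), 2L, 1L))
  dysp <- ifelse(f_dysp,
                 ifelse(bern(sp$dyspnoea_orthopnoea),
                        "orthopnoea_or_new_nocturnal", "worse_on_exercise"),
                 "none_or_improved")

  sys <- runif(n, 100, 140)
  dia <- pmin(runif(n, 55, 85), sys - 15)
  sys[f_hyper] <- runif(sum(f_hyper), 145, 185)
  dia[f_hyper] <- runif(sum(f_hyper), 70, 95)
  sys[f_hypo] <- runif(sum(f_hypo), 78, 88)
  dia[f_hypo] <- runif(sum(f_hypo), 40, 48)

  hr <- runif(n, 60, 100)
  hr[rhythm == "sinus"] <- runif(sum(rhythm == "sinus"), 55, 75)
  hr[f_sinus_t] <- runif(sum(f_sinus_t), 80, 115)
  hr[f_af_t] <- runif(sum(f_af_t), 105, 140)

  wsplit <- sp$weight / sum(sp$weight)
  weight <- rep("stable", n)
  weight[f_weight] <- sample(names(wsplit), sum(f_weight), replace = TRUE, prob = wsplit)

  angina <- ifelse(f_angina,
                   ifelse(bern(sp$angina_progressive), "progressive", "ccs_class3"),
                   "none_or_stable_ccs_le2")

  # NT-proBNP in pmol/l; previous value set so the rise item fires iff drawn
  bnp_cur <- runif(n, 30, 350)
  bnp_cur[f_bnp_level] <- runif(sum(f_bnp_level), 410, 1500)
  bnp_prev <- bnp_cur / runif(n, 0.80, 1.20)
  bnp_prev[f_bnp_rise] <- (bnp_cur / runif(n, 1.30, 2.50))[f_bnp_rise]

  pot <- runif(n, 3.6, 4.9)
  pot[f_pot] <- ifelse(bern(0.5), runif(n, 2.9, 3.4), runif(n, 5.1, 5.9))[f_pot]
  sod <- runif(n, 136, 144)
  sod[f_sod] <- ifelse(bern(0.5), runif(n, 126, 134), runif(n, 146, 151))[f_sod]

  crea <- runif(n, 60, 110)
  crea_prev <- crea * runif(n, 0.85, 1.15)
  gfr <- runif(n, 45, 90)
  crea_mode <- sample(c("high", "rise", "gfr"), n, replace = TRUE)
  m_high <- f_crea & crea_mode == "high"
  m_rise <- f_crea & crea_mode == "rise"
  m_gfr <- f_crea & crea_mode == "gfr"
  crea_prev[m_high] <- runif(sum(m_high), 150, 210)
  crea[m_high] <- runif(sum(m_high), 225, 400)
  crea_prev[m_rise] <- runif(sum(m_rise), 80, 130)
  crea[m_rise] <- crea_prev[m_rise] * runif(sum(m_rise), 1.30, 1.80)
  gfr[m_high | m_rise] <- runif(sum(m_high | m_rise), 35, 60)
  gfr[m_gfr] <- runif(sum(m_gfr), 8, 28)

  hb <- runif(n, 6.6, 10.0)
  hb[f_hb] <- runif(sum(f_hb), 4.6, 6.4)
  chron <- rep(NA_character_, n)
  chron[f_hb] <- ifelse(bern(sp$anaemia_new), "new", "chronic")[f_hb]

  adm6 <- ifelse(f_adm, sample(1:2, n, replace = TRUE), 0L)
  adm12 <- adm6 + ifelse(f_adm, sample(0:1, n, replace = TRUE),
                         rbinom(n, 1, 0.2))

  # --- laboratory missingness ----------------------------------------------
  mp <- cfg$lab_missingness
  blank <- function(x, field) replace(x, runif(n) < mp[[field]], NA)
  bnp_cur <- blank(bnp_cur, "ntprobnp_current")
  bnp_prev <- blank(bnp_prev, "ntprobnp_previous")
  pot <- blank(pot, "potassium")
  sod <- blank(sod, "sodium")
  crea <- blank(crea, "creatinine_current")
  crea_prev <- blank(crea_prev, "creatinine_previous")
  gfr <- blank(gfr, "gfr")
  hb <- blank(hb, "haemoglobin")
  chron <- blank(chron, "anaemia_chronicity")

  cov <- cfg$covariates
  assessments <- tibble::tibble(
    patient_id = sprintf("S%05d", seq_len(n)),
    nyha_class = as.integer(nyha),
    dyspnoea_status = dysp,
    systolic_bp = sys, diastolic_bp = dia,
    hypotension_symptoms = f_hypo,
    rhythm = rhythm, heart_rate = hr,
    rhythm_new_onset = f_new, rhythm_symptomatic = f_sympt,
    weight_status = weight, oedema_present = f_oedema,
    angina_status = angina,
    ntprobnp_current = bnp_cur, ntprobnp_previous = bnp_prev,
    potassium = pot, sodium = sod,
    creatinine_current = crea, creatinine_previous = crea_prev,
    gfr = gfr, haemoglobin = hb, anaemia_chronicity = chron,
    uptitration_incomplete = bern(prev[["uptitration"]]),
    poor_compliance_suspected = bern(prev[["compliance"]]),
    poor_social_support = bern(prev[["social_support"]]),
    depression_signs = bern(prev[["depression"]]),
    hf_admissions_last_6mo = as.integer(adm6),
    hf_admissions_last_12mo = as.integer(adm12),
    age = rnorm(n, cov$age_mean, cov$age_sd),
    sex = ifelse(bern(cov$male_fraction), "male", "female"),
    copd = bern(cov$copd_prevalence),
    diabetes = bern(cov$diabetes_prevalence)
  )

  scored <- mishf_score(assessments[c("patient_id", assessment_fields())])
  out <- dplyr::left_join(
    assessments,
    scored[c("patient_id", "total", "completeness", "stability_class",
             "recommendation", "underestimation_flag")],
    by = "patient_id") |>
    dplyr::mutate(
      score_class = ifelse(.data$stability_class == "stable", "low", "high"),
      care_setting = ifelse(
        runif(n) < ifelse(.data$score_class == "low",
                          cfg$low_to_gp_prob, cfg$high_to_gp_prob),
        "gp", "cardiologist"))

  # --- 1-year outcomes: correlated components, union = composite -----------
  rho <- lapply(cfg$event_rates, function(er) solve_event_rho(er$components, er$composite))
  frailty <- rnorm(n)
  events <- matrix(FALSE, n, 3,
                   dimnames = list(NULL, c("hf_admission", "cardiac_admission", "death")))
  for (cls in c("low", "high")) {
    idx <- which(out$score_class == cls)
    if (!length(idx)) next
    er <- cfg$event_rates[[cls]]
    r <- rho[[cls]]
    s <- sqrt(1 - r^2)
    for (j in colnames(events)) {
      p_j <- er$components[[j]]
      events[idx, j] <- p_j > 0 &
        r * frailty[idx] + s * rnorm(length(idx)) < qnorm(max(p_j, 1e-12))
    }
  }
  out$hf_admission <- events[, "hf_admission"]
  out$cardiac_admission <- events[, "cardiac_admission"]
  out$death <- events[, "death"]
  out$composite <- out$hf_admission | out$cardiac_admission | out$death

  attr(out, "config") <- cfg
  out
}

#' Simulate an independent second rater
#'
#' Emulates the dual-rater reliability design: a second care giver re-scores
#' each patient. The second total is the first plus integer Gaussian noise
#' on the configured scale, clipped to the instrument's valid range, and the
#' stable/unstable class is recomputed from the noisy total. Noise scale 0
#' reproduces the first rater exactly.
#'
#' @param cohort A cohort from [generate_cohort()] (needs `patient_id` and
#'   `total`).
#' @param cfg The [cohort_config()]; uses `rater_disagreement_sd` and
#'   `seed` (offset so the pair draw is independent of the cohort draw).
#' @param thresholds Threshold record for re-classification.
#' @return A tibble: `subject_id`, `rater1_total`, `rater2_total`,
#'   `rater1_class`, `rater2_class`.
#' @export
generate_rater_pairs <- function(cohort, cfg,
                                 thresholds = mishf_thresholds()) {
  stopifnot(is.data.frame(cohort), inherits(cfg, "cohort_config"))
  if (nrow(cohort) == 0) abort("`cohort` must be non-empty")
  if (!is.numeric(cfg$rater_disagreement_sd) || cfg$rater_disagreement_sd < 0) {
    abort("`rater_disagreement_sd` must be non-negative")
  }
  r1 <- cohort$total
  withr::with_seed(cfg$seed + 1L, {
    noise <- as.integer(round(rnorm(nrow(cohort), 0, cfg$rater_disagreement_sd)))
    r2 <- pmin(pmax(r1 + noise, 0L), max_possible_score(thresholds))
    tibble::tibble(
      subject_id = cohort$patient_id,
      rater1_total = as.integer(r1),
      rater2_total = as.integer(r2),
      rater1_class = ifelse(r1 <= thresholds$stable_max, "stable", "unstable"),
      rater2_class = ifelse(r2 <= thresholds$stable_max, "stable", "unstable")
    )
  })
}

#' Patient-level outcome records realising published group counts
#'
#' Constructs a table of per-patient outcome flags whose marginal counts
#' (heart-failure admission, cardiac non-HF admission, death) and composite
#' count (patients with at least one event) match the given values exactly.
#' Events are laid as consecutive wrap-around arcs over the composite
#' patients, so every composite patient has at least one event and the
#' overlap is distributed deterministically. Used to rebuild published
#' outcome tables, which print component and composite counts that overlap
#' within patients.
#'
#' @param n Group size.
#' @param hf_admission,cardiac_admission,death,composite Event counts;
#'   each component must not exceed the composite and the components must
#'   sum to at least the composite.
#' @param score_class,care_setting Labels attached to every row.
#' @return A tibble in the outcome-record schema (`patient_id`,
#'   `score_class`, `care_setting`, `hf_admission`, `cardiac_admission`,
#'   `death`).
#' @examples
#' gp_low <- outcome_records_from_counts(205, 11, 3, 13, 20, "low", "gp")
#' colSums(gp_low[c("hf_admission", "cardiac_admission", "death")])
#' @export
outcome_records_from_counts <- function(n, hf_admission, cardiac_admission,
                                        death, composite,
                                        score_class, care_setting) {
  counts <- c(hf_admission = hf_admission, cardiac_admission = cardiac_admission,
              death = death)
  if (composite > n) abort("`composite` cannot exceed `n`")
  if (any(counts > composite)) abort("No component count can exceed the composite count")
  if (sum(counts) < composite) abort("Component counts must sum to at least the composite")
  flags <- matrix(FALSE, n, 3, dimnames = list(NULL, names(counts)))
  start <- 0
  if (composite > 0) {
    for (j in names(counts)) {
      c_j <- counts[[j]]
      if (c_j > 0) flags[(start + seq_len(c_j) - 1) %% composite + 1, j] <- TRUE
      start <- start + c_j
    }
  }
  tibble::tibble(
    patient_id = sprintf("%s_%s_%04d", score_class, care_setting, seq_len(n)),
    score_class = score_class, care_setting = care_setting,
    hf_admission = flags[, "hf_admission"],
    cardiac_admission = flags[, "cardiac_admission"],
    death = flags[, "death"]
  )
}
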