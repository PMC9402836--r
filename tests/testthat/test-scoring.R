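test_that("a fully normal assessment scores zero on every item", {
  res <- mishf_score(normal_assessment())
  long <- score_items(normal_assessment())
  expect_true(all(long$points == 0L))
  expect_true(all(long$assessed))
  expect_equal(res$total, 0L)
  expect_equal(res$completeness, 1)
  expect_equal(res$stability_class, "stable")
  expect_equal(res$recommendation, "primary_care")
  expect_false(res$underestimation_flag)
})

test_that("every item fires with its published points", {
  cases <- list(
    list("nyha", 1L, list(nyha_class = 3L)),
    list("nyha", 3L, list(nyha_class = 4L)),
    list("dyspnoea", 1L, list(dyspnoea_status = "worse_on_exercise")),
    list("dyspnoea", 3L, list(dyspnoea_status = "orthopnoea_or_new_nocturnal")),
    list("bp_hypotension", 1L, list(systolic_bp = 85, diastolic_bp = 45,
                                    hypotension_symptoms = TRUE)),
    list("bp_hypotension", 0L, list(systolic_bp = 85, diastolic_bp = 45)),
    list("bp_hypotension", 0L, list(systolic_bp = 85, hypotension_symptoms = TRUE)),
    list("bp_hypertension", 1L, list(systolic_bp = 150)),
    list("bp_hypertension", 1L, list(systolic_bp = 120, diastolic_bp = 90)),
    list("bp_hypertension", 0L, list(systolic_bp = 140, diastolic_bp = 85)),
    list("hr_sinus", 2L, list(heart_rate = 80)),
    list("hr_sinus", 0L, list(heart_rate = 75)),
    list("hr_af", 2L, list(rhythm = "atrial_fibrillation", heart_rate = 110)),
    list("hr_af", 0L, list(rhythm = "atrial_fibrillation", heart_rate = 100)),
    list("rhythm_new", 2L, list(rhythm = "other_irregular", rhythm_new_onset = TRUE)),
    list("rhythm_new", 0L, list(rhythm_new_onset = TRUE)), # sinus rhythm is not irregular
    list("rhythm_symptomatic", 2L, list(rhythm = "atrial_fibrillation",
                                        rhythm_symptomatic = TRUE)),
    list("weight", 1L, list(weight_status = "increased_gt2kg_1week")),
    list("weight", 1L, list(weight_status = "decreased")),
    list("weight", 2L, list(weight_status = "decreased_with_cachexia")),
    list("oedema", 1L, list(oedema_present = TRUE)),
    list("angina", 3L, list(angina_status = "progressive")),
    list("angina", 2L, list(angina_status = "ccs_class3")),
    list("ntprobnp_rise", 1L, list(ntprobnp_current = 300, ntprobnp_previous = 200)),
    list("ntprobnp_rise", 0L, list(ntprobnp_current = 250, ntprobnp_previous = 200)),
    list("ntprobnp_level", 1L, list(ntprobnp_current = 450, ntprobnp_previous = 450)),
    list("ntprobnp_level", 0L, list(ntprobnp_current = 400, ntprobnp_previous = 400)),
    list("potassium", 1L, list(potassium = 3.2)),
    list("potassium", 1L, list(potassium = 5.5)),
    list("potassium", 0L, list(potassium = 3.5)),
    list("potassium", 0L, list(potassium = 5.0)),
    list("sodium", 1L, list(sodium = 130)),
    list("sodium", 1L, list(sodium = 146)),
    list("sodium", 0L, list(sodium = 135)),
    list("creatinine", 1L, list(creatinine_current = 250, creatinine_previous = 240)),
    list("creatinine", 1L, list(creatinine_current = 130, creatinine_previous = 100)),
    list("creatinine", 1L, list(gfr = 25)),
    list("creatinine", 0L, list(creatinine_current = 220, creatinine_previous = 220)),
    list("haemoglobin", 2L, list(haemoglobin = 6.0, anaemia_chronicity = "new")),
    list("haemoglobin", 1L, list(haemoglobin = 6.0, anaemia_chronicity = "chronic")),
    list("haemoglobin", 1L, list(haemoglobin = 6.0)), # chronicity unknown -> chronic
    list("haemoglobin", 0L, list(haemoglobin = 6.5, anaemia_chronicity = "new")),
    list("uptitration", 1L, list(uptitration_incomplete = TRUE)),
    list("compliance", 1L, list(poor_compliance_suspected = TRUE)),
    list("social_support", 1L, list(poor_social_support = TRUE)),
    list("depression", 1L, list(depression_signs = TRUE)),
    list("hf_admission", 2L, list(hf_admissions_last_6mo = 1L,
                                  hf_admissions_last_12mo = 1L)),
    list("hf_admission", 2L, list(hf_admissions_last_12mo = 2L)),
    list("hf_admission", 0L, list(hf_admissions_last_12mo = 1L))
  )
  for (cs in cases) {
    got <- do.call(item_points, c(list(item = cs[[1]]), cs[[3]]))
    expect_identical(got, cs[[2]],
                     label = paste0(cs[[1]], " with ",
                                    paste(names(cs[[3]]), unlist(cs[[3]]),
                                          sep = "=", collapse = ", ")))
  }
})

test_that("the creatinine item fires at most once, the NT-proBNP items add", {
  # all three renal sub-criteria hold -> still 1 point
  expect_identical(item_points("creatinine", creatinine_current = 250,
                               creatinine_previous = 100, gfr = 20), 1L)
  # rise and level are independent items and may both fire
  s <- mishf_score(assessment_with(ntprobnp_current = 600, ntprobnp_previous = 300))
  expect_identical(s$ntprobnp_rise + s$ntprobnp_level, 2L)
  expect_identical(s$total, 2L)
})

test_that("rhythm items add on top of the rate item", {
  s <- mishf_score(assessment_with(rhythm = "atrial_fibrillation", heart_rate = 120,
                                   rhythm_new_onset = TRUE, rhythm_symptomatic = TRUE))
  expect_identical(s$hr_af, 2L)
  expect_identical(s$rhythm_new, 2L)
  expect_identical(s$rhythm_symptomatic, 2L)
  expect_identical(s$total, 6L)
})

test_that("the stability threshold separates totals 0-2 from 3 and above", {
  # single 3-point item
  s3 <- mishf_score(assessment_with(nyha_class = 4L))
  expect_identical(s3$total, 3L)
  expect_equal(s3$stability_class, "unstable")
  expect_equal(s3$recommendation, "specialist_care")
  # total exactly 2 is still stable
  s2 <- mishf_score(assessment_with(oedema_present = TRUE, potassium = 3.2))
  expect_identical(s2$total, 2L)
  expect_equal(s2$stability_class, "stable")
  expect_equal(s2$recommendation, "primary_care")
  # sweep: class always matches the threshold on generated patients
  co <- generate_cohort(cohort_config(n_patients = 500, seed = 11))
  expect_equal(co$stability_class, ifelse(co$total <= 2, "stable", "unstable"))
})

test_that("missing laboratory values are unassessed, score zero and flag underestimation", {
  a <- assessment_with(potassium = NA_real_, ntprobnp_current = NA_real_,
                       ntprobnp_previous = NA_real_)
  long <- score_items(a)
  unass <- long$item_id[!long$assessed]
  expect_setequal(unass, c("potassium", "ntprobnp_rise", "ntprobnp_level"))
  expect_true(all(long$points[!long$assessed] == 0L))
  s <- mishf_score(a)
  expect_true(s$underestimation_flag) # labs missing and total in stable range
  expect_lt(s$completeness, 1)
  # an unstable total switches the flag off
  s2 <- mishf_score(assessment_with(potassium = NA_real_, nyha_class = 4L))
  expect_false(s2$underestimation_flag)
  # a missing previous value alone leaves the rise item unassessed
  long3 <- score_items(assessment_with(ntprobnp_previous = NA_real_))
  expect_false(long3$assessed[long3$item_id == "ntprobnp_rise"])
  expect_true(long3$assessed[long3$item_id == "ntprobnp_level"])
})

test_that("removing any optional lab value never increases the total", {
  co <- generate_cohort(cohort_config(n_patients = 150, seed = 3))
  a <- co[c("patient_id", assessment_fields())]
  base_total <- mishf_score(a)$total
  optional <- c("ntprobnp_current", "ntprobnp_previous", "potassium", "sodium",
                "creatinine_current", "creatinine_previous", "gfr",
                "haemoglobin", "anaemia_chronicity")
  for (f in optional) {
    dropped <- a
    dropped[[f]] <- NA
    expect_true(all(mishf_score(dropped)$total <= base_total), label = f)
  }
})

test_that("scoring is deterministic and respects the maximum possible total", {
  co <- generate_cohort(cohort_config(n_patients = 400, seed = 21))
  a <- co[c("patient_id", assessment_fields())]
  s1 <- mishf_score(a)
  s2 <- mishf_score(a)
  expect_identical(s1, s2)
  expect_true(all(s1$total >= 0L))
  expect_true(all(s1$total <= max_possible_score()))
  expect_true(all(s1$total == round(s1$total)))
})

test_that("max_possible_score matches exhaustive enumeration over the assessment lattice", {
  # options per clinical dimension; scoring is additive across dimensions, so
  # the maximum is the sum of per-dimension maxima found by brute force
  option_sets <- list(
    list(list(nyha_class = 1L), list(nyha_class = 2L), list(nyha_class = 3L),
         list(nyha_class = 4L)),
    lapply(mishf:::mishf_enums$dyspnoea_status, function(v) list(dyspnoea_status = v)),
    list(list(systolic_bp = 120, diastolic_bp = 80),
         list(systolic_bp = 85, diastolic_bp = 45, hypotension_symptoms = TRUE),
         list(systolic_bp = 160, diastolic_bp = 95)),
    # rhythm x rate x new x symptomatic
    unlist(recursive = FALSE, lapply(
      list(list(rhythm = "sinus", heart_rate = 70), list(rhythm = "sinus", heart_rate = 90),
           list(rhythm = "atrial_fibrillation", heart_rate = 90),
           list(rhythm = "atrial_fibrillation", heart_rate = 120),
           list(rhythm = "other_irregular", heart_rate = 90)),
      function(r) list(r, c(r, list(rhythm_new_onset = TRUE, rhythm_symptomatic = TRUE))))),
    lapply(mishf:::mishf_enums$weight_status, function(v) list(weight_status = v)),
    list(list(oedema_present = FALSE), list(oedema_present = TRUE)),
    lapply(mishf:::mishf_enums$angina_status, function(v) list(angina_status = v)),
    list(list(ntprobnp_current = 200, ntprobnp_previous = 200),
         list(ntprobnp_current = 600, ntprobnp_previous = 300)),
    list(list(potassium = 4.2), list(potassium = 3.0)),
    list(list(sodium = 140), list(sodium = 130)),
    list(list(creatinine_current = 90), list(creatinine_current = 250, gfr = 20)),
    list(list(haemoglobin = 8), list(haemoglobin = 6, anaemia_chronicity = "new"),
         list(haemoglobin = 6, anaemia_chronicity = "chronic")),
    list(list(uptitration_incomplete = FALSE), list(uptitration_incomplete = TRUE)),
    list(list(poor_compliance_suspected = FALSE), list(poor_compliance_suspected = TRUE)),
    list(list(poor_social_support = FALSE), list(poor_social_support = TRUE)),
    list(list(depression_signs = FALSE), list(depression_signs = TRUE)),
    list(list(hf_admissions_last_6mo = 0L, hf_admissions_last_12mo = 0L),
         list(hf_admissions_last_6mo = 2L, hf_admissions_last_12mo = 3L))
  )
  dim_max <- vapply(option_sets, function(opts) {
    max(vapply(opts, function(o) do.call(assessment_with, o) |> mishf_score() |>
                 (\(s) s$total)(), integer(1)))
  }, integer(1))
  expect_identical(sum(dim_max), max_possible_score())
})

test_that("reduced rule sets lower or preserve the maximum", {
  items <- mishf_items()
  # force all rhythm-related items mutually exclusive
  merged <- items
  merged$exclusive_group[merged$exclusive_group %in%
    c("heart_rate", "rhythm_new", "rhythm_symptomatic")] <- "heart_rate"
  expect_lte(max_possible_score(items = merged), max_possible_score())
  # single-item rule set
  expect_identical(max_possible_score(items = items[items$item_id == "nyha", ]), 3L)
})

test_that("invalid assessments are rejected with the offending field named", {
  expect_error(mishf_score(assessment_with(nyha_class = 5L)), "nyha_class")
  expect_error(mishf_score(assessment_with(heart_rate = -10)), "heart_rate")
  expect_error(mishf_score(assessment_with(systolic_bp = 80, diastolic_bp = 90)),
               "diastolic_bp")
  expect_error(mishf_score(assessment_with(angina_status = "ccs_class4")),
               "specialist")
  expect_error(mishf_score(assessment_with(hf_admissions_last_6mo = 2L,
                                           hf_admissions_last_12mo = 1L)),
               "hf_admissions")
  expect_error(mishf_score(assessment_with(weight_status = "ballooning")),
               "weight_status")
  expect_error(mishf_score(dplyr::select(normal_assessment(), -"rhythm")),
               "rhythm")
})

test_that("lenient validation drops bad rows but keeps good ones", {
  d <- dplyr::bind_rows(normal_assessment(), assessment_with(nyha_class = 9L))
  d$patient_id <- c("A", "B")
  out <- validate_assessments(d, lenient = TRUE)
  expect_equal(out$patient_id, "A")
  expect_equal(attr(out, "problems")$row, 2L)
  expect_equal(attr(out, "problems")$field, "nyha_class")
})
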