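test_that("visit classification respects thresholds and missingness", {
  visits <- tiny_cohort()
  fpg <- classify_t2d(visits, "fpg")
  hba <- classify_t2d(visits, "hba1c")
  # boundary value is a case (inclusive >=)
  expect_equal(fpg$t2d_status[fpg$participant_id == "E"], "case")
  # below threshold is a noncase
  expect_equal(hba$t2d_status[hba$participant_id == "B" &
                                hba$visit_index == 1], "noncase")
  # missing analyte is indeterminate, never a silent noncase
  expect_true(all(fpg$t2d_status[fpg$participant_id == "D"] == "indeterminate"))
  # discordant participant: noncase by FPG, case by HbA1c
  expect_equal(fpg$t2d_status[fpg$participant_id == "G"], "noncase")
  expect_equal(hba$t2d_status[hba$participant_id == "G"], "case")
})

test_that("assembly picks first-diagnosis visit, baseline for noncases, and excludes correctly", {
  visits <- tiny_cohort()
  suppressMessages(expect_warning(
    cohort <- assemble_analysis_dataset(visits, "fpg"),
    "baseline"
  ))
  # B converts at visit 2: record taken there
  b <- cohort[cohort$participant_id == "B", ]
  expect_true(b$case)
  expect_equal(b$index_visit, 2L)
  expect_equal(b$age, 65)
  # A noncase throughout: baseline record
  a <- cohort[cohort$participant_id == "A", ]
  expect_false(a$case)
  expect_equal(a$index_visit, 1L)
  # C (medication), D (indeterminate), F (no baseline) excluded
  expect_setequal(cohort$participant_id, c("A", "B", "E", "G"))
  ex <- exclusions(cohort)
  expect_equal(ex$reason[ex$participant_id == "C"], "diabetes_medication")
  expect_equal(ex$reason[ex$participant_id == "D"], "analyte_missing_all_visits")
  expect_equal(ex$reason[ex$participant_id == "F"],
               "noncase_without_baseline_visit")
  expect_equal(attr(cohort, "n_cases"), 2)
  expect_error(assemble_analysis_dataset(visits[0, ], "fpg"), "Empty")
})

test_that("assembly is idempotent on its own single-visit output", {
  visits <- tiny_cohort()
  suppressMessages(suppressWarnings(
    cohort <- assemble_analysis_dataset(visits, "fpg")
  ))
  again <- suppressWarnings(
    assemble_analysis_dataset(cohort[names(tiny_cohort())], "fpg")
  )
  shared <- c("participant_id", "case", "age", "fpg", "hba1c")
  expect_equal(again[shared], cohort[shared], ignore_attr = TRUE)
})

test_that("clinical hypertension composes self-report, medication and measured BP", {
  df <- tibble::tibble(
    hypertension = c("no", "yes", "no", NA, "no", NA),
    bp_medication = c("no", "no", "yes", NA, "no", NA),
    systolic_bp = c(120, 120, 120, 150, NA, NA),
    diastolic_bp = c(75, 75, 75, 80, 95, NA)
  )
  expect_equal(derive_hypertension <- t2dval:::derive_hypertension(df),
               c(FALSE, TRUE, TRUE, TRUE, TRUE, NA))
})

test_that("complete-case filtering is model-specific and errors on degenerate cohorts", {
  visits <- tiny_cohort()
  visits$family_history_dm[visits$participant_id == "A"] <- NA
  suppressMessages(suppressWarnings(
    cohort <- assemble_analysis_dataset(visits, "fpg")
  ))
  adrs <- bundled_score_specs("ADRS")[[1]]
  cc_adrs <- complete_case_filter(cohort, adrs)
  # family history is not an ADRS predictor: A retained
  expect_true("A" %in% cc_adrs$participant_id)
  expect_equal(attr(cc_adrs, "excluded_missing"), 0)

  fh_spec <- score_spec(
    name = "NEEDS_FH", form = "points",
    probability_link = list(type = "score_logistic", a = -3, b = 0.5),
    items = list(list(predictor = "family_history_dm",
                      kind = "categorical_points",
                      levels = list(yes = 5, no = 0)))
  )
  cc_fh <- complete_case_filter(cohort, fh_spec)
  expect_false("A" %in% cc_fh$participant_id)
  expect_equal(attr(cc_fh, "excluded_missing"), 1)

  # dropping every noncase must error, naming the model
  only_cases <- cohort[cohort$case, ]
  expect_error(complete_case_filter(only_cases, adrs), "ADRS")
})

test_that("stratification splits at the documented cut points with ties upward", {
  cohort <- tibble::tibble(
    participant_id = letters[1:5],
    age = c(40, 50, 51, 60, 70), bmi = c(22, 25, 27, 30, 24),
    sex = c("male", "female", "female", "female", "male"),
    residency = c("rural", "urban", "rural", "rural", "urban"),
    case = c(TRUE, FALSE, TRUE, FALSE, TRUE)
  )
  s_age <- suppressWarnings(stratify(cohort, "age_median"))
  # median 51; the tie goes to the upper group
  expect_setequal(s_age[[1]]$participant_id, c("a", "b"))
  expect_setequal(s_age[[2]]$participant_id, c("c", "d", "e"))
  s_bmi <- suppressWarnings(stratify(cohort, "bmi_25"))
  expect_true("b" %in% s_bmi[["bmi>=25"]]$participant_id) # 25.0 is upper
  # missing axis values are dropped with a warning and counted
  cohort$bmi[1] <- NA
  w <- capture_warnings(s2 <- stratify(cohort, "bmi_25"))
  expect_match(w, "missing", all = FALSE)
  expect_equal(nrow(s2[[1]]) + nrow(s2[[2]]) + attr(s2, "dropped"),
               nrow(cohort))
})

test_that("minimum-events rule passes at 100/100 and warns below", {
  mk <- function(cases, noncases) {
    tibble::tibble(case = rep(c(TRUE, FALSE), c(cases, noncases)))
  }
  expect_equal(check_min_events(mk(100, 620))$status, "pass")
  expect_equal(check_min_events(mk(49, 371))$status, "warn")
  expect_equal(check_min_events(mk(0, 100))$status, "warn")
  expect_match(check_min_events(mk(49, 371))$message, "49 events")
})

test_that("cohort CSV dialect round-trips with empty-string missing values", {
  visits <- tiny_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(visits, path)
  expect_false(any(grepl("NA", readLines(path), fixed = TRUE)))
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(visits))
})
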