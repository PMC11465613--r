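test_that("point scores sum item points per the specification", {
  spec <- points_spec_3item()
  rec <- tibble::tibble(age = 60, waist_circumference = 95,
                        hypertension_clinical = TRUE, sex = "male")
  expect_equal(evaluate_score(spec, rec), 6)
  # below every cut point
  rec2 <- tibble::tibble(age = 40, waist_circumference = 80,
                         hypertension_clinical = FALSE, sex = "male")
  expect_equal(evaluate_score(spec, rec2), 0)
  # missing required predictor yields NA, never a default
  rec3 <- tibble::tibble(age = 60, waist_circumference = NA_real_,
                         hypertension_clinical = TRUE, sex = "male")
  expect_true(is.na(evaluate_score(spec, rec3)))
})

test_that("logistic form builds the linear predictor and maps through plogis", {
  spec <- score_spec(
    name = "LIN", form = "logistic", intercept = -3,
    items = list(list(predictor = "age", kind = "linear_coefficient",
                      coefficient = 0.05))
  )
  raw <- evaluate_score(spec, tibble::tibble(age = 40))
  expect_equal(raw, -1)
  expect_equal(score_to_probability(spec, raw), 0.2689414, tolerance = 1e-6)
  expect_equal(score_to_probability(spec, 0), 0.5)
})

test_that("score_logistic link is increasing and rejects non-positive slope", {
  spec <- points_spec_3item()
  s <- 0:6
  p <- score_to_probability(spec, s)
  expect_true(all(diff(p) > 0))
  expect_equal(score_to_probability(spec, 6), plogis(-3 + 0.5 * 6))
  bad <- spec
  bad$probability_link$b <- -1
  expect_error(score_to_probability(bad, 3), "b must be > 0")
})

test_that("sex-specific cut points and lower-inclusive intervals are honoured", {
  findrisc <- bundled_score_specs("SIMPLIFIED_FINDRISC")[[1]]
  base <- tibble::tibble(
    age = 44, bmi = 24, bp_medication = "no", family_history_dm = "no",
    sex = "female", waist_circumference = 80
  )
  male <- dplyr::mutate(base, sex = "male")
  # WC 80 reaches the first female band (cut 80, lower-inclusive) but not male (94)
  expect_equal(evaluate_score(findrisc, base), 3)
  expect_equal(evaluate_score(findrisc, male), 0)
  # age 45 enters the 45-54 band exactly at the bound
  expect_equal(evaluate_score(findrisc, dplyr::mutate(male, age = 45)), 2)
})

test_that("scores are invariant to fields the spec does not name", {
  spec <- points_spec_3item()
  rec <- tibble::tibble(age = 60, waist_circumference = 95,
                        hypertension_clinical = TRUE, sex = "male")
  noisy <- dplyr::mutate(rec, bmi = 99, residency = "urban", fpg = 12)
  expect_identical(evaluate_score(spec, rec), evaluate_score(spec, noisy))
})

test_that("raising a positively weighted predictor never lowers the probability", {
  specs <- bundled_score_specs()
  set.seed(41)
  for (spec in specs) {
    base <- tibble::tibble(
      age = runif(20, 35, 75), bmi = runif(20, 20, 35),
      waist_circumference = runif(20, 70, 110),
      sex = sample(c("male", "female"), 20, TRUE),
      bp_medication = sample(c("yes", "no"), 20, TRUE),
      hypertension_clinical = sample(c(TRUE, FALSE), 20, TRUE),
      family_history_dm = sample(c("yes", "no"), 20, TRUE),
      physical_activity = sample(1:3, 20, TRUE)
    )
    bumped <- dplyr::mutate(base, age = age + 10,
                            waist_circumference = waist_circumference + 15)
    p0 <- score_to_probability(spec, evaluate_score(spec, base))
    p1 <- score_to_probability(spec, evaluate_score(spec, bumped))
    expect_true(all(p1 >= p0), label = paste("monotonicity for", spec$name))
  }
})

test_that("score specs survive a serialisation round trip identically", {
  for (fmt in c(".json", ".yaml")) {
    spec <- bundled_score_specs("IRS")[[1]]
    path <- withr::local_tempfile(fileext = fmt)
    write_score_spec(spec, path)
    expect_equal(load_score_spec(path), spec)
  }
})

test_that("spec validation reports field paths for malformed inputs", {
  raw <- list(
    name = "BAD", form = "points",
    probability_link = list(type = "score_logistic", a = -3, b = 0.5),
    items = list(list(predictor = "age", kind = "categorical_points",
                      cut_points = c(50, 40), values = c(0, 1, 2)))
  )
  expect_error(validate_score_spec(raw), "items\\[1\\].cut_points")
  raw$items[[1]]$cut_points <- c(40, 50)
  raw$items[[1]]$values <- c(0, 1) # one value missing for 3 intervals
  expect_error(validate_score_spec(raw), "one value per interval")
  raw$items[[1]]$values <- c(0, 1, 2)
  raw$items[[1]]$predictor <- "shoe_size"
  expect_error(validate_score_spec(raw), "unknown predictor")
})

test_that("bundled specs have the documented structure", {
  specs <- bundled_score_specs()
  n_items <- vapply(specs, function(s) length(s$items), integer(1))
  expect_equal(unname(n_items), c(3L, 5L, 6L, 4L)) # ADRS, FINDRISC, ADA, IRS
  has_htn <- vapply(specs, function(s) {
    any(vapply(s$items, function(it) it$predictor == "hypertension",
               logical(1)))
  }, logical(1))
  expect_equal(unname(has_htn), c(TRUE, TRUE, TRUE, FALSE)) # IRS excludes it
  expect_setequal(
    vapply(specs$ADRS$items, `[[`, character(1), "predictor"),
    c("age", "waist_circumference", "hypertension")
  )
  expect_true(all(vapply(specs, `[[`, logical(1), "provisional")))
})

test_that("cohort scoring is total and order-preserving", {
  co <- generate_cohort(sim_config(n_participants = 150), seed = 5)
  suppressMessages(suppressWarnings(
    cohort <- assemble_analysis_dataset(co, "fpg")
  ))
  spec <- bundled_score_specs("ADRS")[[1]]
  cc <- complete_case_filter(cohort, spec)
  scored <- score_cohort(cc, spec)
  expect_equal(nrow(scored), nrow(cc))
  expect_identical(scored$participant_id, cc$participant_id)
  perm <- sample(nrow(cc))
  scored_perm <- score_cohort(cc[perm, ], spec)
  expect_equal(scored_perm$probability, scored$probability[perm])
  expect_true(all(scored$probability > 0 & scored$probability < 1))
})
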