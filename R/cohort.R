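#' Diagnostic criteria for screen-detected type 2 diabetes
#'
#' Returns the fixed glycaemic criterion used to classify prevalent
#' undiagnosed type 2 diabetes: fasting plasma glucose (FPG)
#' >= 7 mmol/L, or HbA1c >= 6.5%. Both thresholds are inclusive and
#' follow current diagnostic guidelines.
#'
#' @param name `"fpg"` or `"hba1c"`.
#' @return A list with elements `name`, `analyte` (the cohort column
#'   holding the analyte), `threshold` and `inclusive`.
#' @examples
#' diagnostic_criterion("fpg")$threshold # 7 mmol/L
#' @export
diagnostic_criterion <- function(name = c("fpg", "hba1c")) {
  name <- tolower(name)
  name <- match.arg(name)
  switch(name,
    fpg = list(name = "fpg", analyte = "fpg", threshold = 7.0, inclusive = TRUE,
               unit = "mmol/L"),
    hba1c = list(name = "hba1c", analyte = "hba1c", threshold = 6.5,
                 inclusive = TRUE, unit = "%")
  )
}

visit_columns <- c(
  "participant_id", "visit_index", "age", "sex", "waist_circumference",
  "bmi", "systolic_bp", "diastolic_bp", "bp_medication", "hypertension",
  "family_history_dm", "physical_activity", "residency",
  "diabetes_medication", "fpg", "hba1c"
)

#' Classify visits against a diagnostic criterion
#'
#' Applies one glycaemic criterion to each visit row. A visit is a
#' `case` when the criterion's analyte is present and at or above the
#' threshold, a `noncase` when present and below it, and `indeterminate`
#' when the analyte is missing — never silently a noncase.
#'
#' @param data A data frame of visit rows (see [read_cohort()] for the
#'   column dictionary).
#' @param criterion `"fpg"` or `"hba1c"`, or a list from
#'   [diagnostic_criterion()].
#' @return `data` with an added `t2d_status` column
#'   (`"case"`/`"noncase"`/`"indeterminate"`).
#' @export
classify_t2d <- function(data, criterion = c("fpg", "hba1c")) {
  crit <- if (is.list(criterion)) criterion else diagnostic_criterion(criterion)
  x <- data[[crit$analyte]]
  if (is.null(x)) abort(sprintf("Column `%s` not found.", crit$analyte))
  status <- ifelse(is.na(x), "indeterminate",
                   ifelse(x >= crit$threshold, "case", "noncase"))
  dplyr::mutate(as_tibble(data), t2d_status = status)
}

# Clinical hypertension: self-reported hypertension, or BP-lowering
# medication, or measured BP >= 140/90. "yes" dominates missingness; "no"
# requires every component determinately negative.
derive_hypertension <- function(data) {
  rep_htn <- yn_to_lgl(data$hypertension)
  med <- yn_to_lgl(data$bp_medication)
  sbp_hi <- data$systolic_bp >= 140
  dbp_hi <- data$diastolic_bp >= 90
  bp_hi <- dplyr::case_when(
    isTRUE_v(sbp_hi) | isTRUE_v(dbp_hi) ~ TRUE,
    !is.na(sbp_hi) & !is.na(dbp_hi) & !sbp_hi & !dbp_hi ~ FALSE,
    TRUE ~ NA
  )
  any_yes <- isTRUE_v(rep_htn) | isTRUE_v(med) | isTRUE_v(bp_hi)
  all_no <- !is.na(rep_htn) & !rep_htn & !is.na(med) & !med &
    !is.na(bp_hi) & !bp_hi
  ifelse(any_yes, TRUE, ifelse(all_no, FALSE, NA))
}

isTRUE_v <- function(x) !is.na(x) & x

#' Assemble the analysis dataset under one diagnostic criterion
#'
#' Reduces a longitudinal cohort (up to three visits per participant) to
#' one analysis record per participant: cases contribute the earliest
#' visit at which the criterion is met ("first time of diagnosis"),
#' noncases contribute their baseline (visit 1) record. Participants on
#' diabetes medication at any visit are excluded, as are participants
#' whose analyte is missing at every visit (logged, never imputed). A
#' participant is a noncase only if below threshold at every visit where
#' the analyte is present.
#'
#' @param data Visit-level data frame.
#' @param criterion `"fpg"` or `"hba1c"`.
#' @return A tibble of analysis records (one row per participant) with
#'   derived columns `case`, `index_visit`, `hypertension_clinical`,
#'   `age_group`, `bmi_group`, and attributes `criterion`, `exclusions`
#'   (a tibble of participant_id/reason) and `n_cases`.
#' @export
assemble_analysis_dataset <- function(data, criterion = c("fpg", "hba1c")) {
  if (is.null(data) || nrow(data) == 0) abort("Empty cohort input.")
  crit <- if (is.list(criterion)) criterion else diagnostic_criterion(criterion)
  data <- as_tibble(data)
  missing_cols <- setdiff(c("participant_id", "visit_index", crit$analyte,
                            "diabetes_medication"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing cohort columns: ", paste(missing_cols, collapse = ", ")))
  }

  data <- classify_t2d(data, crit)
  med <- yn_to_lgl(data$diabetes_medication)
  med_ids <- unique(data$participant_id[isTRUE_v(med)])

  work <- dplyr::filter(data, !.data$participant_id %in% med_ids)

  per <- work %>%
    group_by(.data$participant_id) %>%
    summarise(
      any_case = any(.data$t2d_status == "case"),
      any_present = any(.data$t2d_status != "indeterminate"),
      first_case_visit = if (any(.data$t2d_status == "case")) {
        min(.data$visit_index[.data$t2d_status == "case"])
      } else NA_integer_,
      has_baseline = any(.data$visit_index == 1L),
      .groups = "drop"
    )

  indeterminate_ids <- per$participant_id[!per$any_present]
  no_baseline_ids <- per$participant_id[per$any_present & !per$any_case &
                                          !per$has_baseline]
  if (length(no_baseline_ids) > 0) {
    warn(sprintf(
      "%d noncase participant(s) without a baseline (visit 1) record excluded.",
      length(no_baseline_ids)
    ))
  }
  if (length(indeterminate_ids) > 0) {
    inform(sprintf(
      "%d participant(s) with %s missing at every visit excluded.",
      length(indeterminate_ids), toupper(crit$name)
    ))
  }

  per <- dplyr::filter(per, .data$any_present,
                       .data$any_case | .data$has_baseline)
  per$index_visit <- ifelse(per$any_case, per$first_case_visit, 1L)

  records <- work %>%
    dplyr::inner_join(
      dplyr::select(per, "participant_id", "index_visit", case = "any_case"),
      by = "participant_id"
    ) %>%
    dplyr::filter(.data$visit_index == .data$index_visit) %>%
    dplyr::select(-"t2d_status")

  records$hypertension_clinical <- derive_hypertension(records)

  age_med <- median(records$age, na.rm = TRUE)
  records <- records %>%
    mutate(
      age_group = ifelse(is.na(.data$age), NA_character_,
                         ifelse(.data$age >= age_med, ">=median", "<median")),
      bmi_group = ifelse(is.na(.data$bmi), NA_character_,
                         ifelse(.data$bmi >= 25, ">=25", "<25"))
    ) %>%
    arrange(.data$participant_id)

  exclusions <- bind_rows(
    tibble(participant_id = med_ids, reason = "diabetes_medication"),
    tibble(participant_id = indeterminate_ids,
           reason = "analyte_missing_all_visits"),
    tibble(participant_id = no_baseline_ids,
           reason = "noncase_without_baseline_visit")
  )

  structure(
    records,
    criterion = crit,
    exclusions = exclusions,
    age_median = age_med,
    n_cases = sum(records$case),
    class = c("t2d_analysis", class(records))
  )
}

#' Exclusion audit trail of an assembled cohort
#'
#' @param cohort Output of [assemble_analysis_dataset()].
#' @return Tibble with `participant_id` and `reason`.
#' @export
exclusions <- function(cohort) {
  attr(cohort, "exclusions") %||%
    tibble(participant_id = character(), reason = character())
}

#' Write the exclusion log as a plain-text audit trail
#'
#' @param cohort Assembled cohort.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(cohort, path) {
  ex <- exclusions(cohort)
  writeLines(sprintf("%s\t%s", ex$participant_id, ex$reason), path)
  invisible(path)
}

#' Model-specific complete-case filter
#'
#' Keeps only records in which every predictor a score requires is
#' non-missing; exclusions based on missing data are model-specific, so
#' each score is validated on its own complete-case cohort. The
#' hypertension predictor is resolved according to the score's declared
#' hypertension definition (clinical composite vs. blood-pressure
#' medication only).
#'
#' @param cohort Assembled analysis cohort.
#' @param spec A score specification ([load_score_spec()]).
#' @return The filtered cohort; attribute `excluded_missing` records the
#'   number of dropped rows. Errors if the result has zero cases or zero
#'   noncases.
#' @export
complete_case_filter <- function(cohort, spec) {
  cols <- required_columns(spec)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort lacks columns required by ", spec$name, ": ",
                 paste(missing_cols, collapse = ", ")))
  }
  keep <- rep(TRUE, nrow(cohort))
  for (cl in cols) keep <- keep & !is.na(cohort[[cl]])
  out <- cohort[keep, , drop = FALSE]
  if (sum(out$case) == 0 || sum(!out$case) == 0) {
    abort(sprintf(
      "Complete-case cohort for model %s has %d cases and %d noncases; both must be positive.",
      spec$name, sum(out$case), sum(!out$case)
    ))
  }
  attr(out, "excluded_missing") <- sum(!keep)
  attr(out, "criterion") <- attr(cohort, "criterion")
  attr(out, "exclusions") <- attr(cohort, "exclusions")
  attr(out, "n_cases") <- sum(out$case)
  out
}

#' Split an analysis cohort into two subgroup strata
#'
#' Splits by sex, median age (computed on the cohort handed in, ties to
#' the upper group), BMI at the fixed 25 kg/m2 cut (ties upper), or
#' rural/urban residency. Records missing the axis variable are dropped
#' with a warning; the two strata partition the retained records.
#'
#' @param cohort Analysis cohort (typically after [complete_case_filter()]).
#' @param axis One of `"sex"`, `"age_median"`, `"bmi_25"`, `"residency"`.
#' @return Named list of two cohort tibbles; attribute `dropped` counts
#'   records lost to a missing axis variable. A stratum with fewer than
#'   10 cases triggers a warning.
#' @export
stratify <- function(cohort, axis = c("sex", "age_median", "bmi_25", "residency")) {
  axis <- match.arg(axis)
  split_info <- switch(axis,
    sex = list(var = cohort$sex,
               levels = c(men = "male", women = "female")),
    age_median = {
      md <- median(cohort$age, na.rm = TRUE)
      list(var = ifelse(cohort$age >= md, "upper", "lower"),
           levels = c(stats::setNames("lower", sprintf("age<%.3g", md)),
                      stats::setNames("upper", sprintf("age>=%.3g", md))))
    },
    bmi_25 = list(var = ifelse(cohort$bmi >= 25, "upper", "lower"),
                  levels = c("bmi<25" = "lower", "bmi>=25" = "upper")),
    residency = list(var = cohort$residency,
                     levels = c(rural = "rural", urban = "urban"))
  )
  keep <- !is.na(split_info$var)
  if (any(!keep)) {
    warn(sprintf("%d record(s) dropped: missing %s.", sum(!keep), axis))
  }
  kept <- cohort[keep, , drop = FALSE]
  out <- lapply(split_info$levels, function(lv) {
    s <- kept[split_info$var[keep] == lv, , drop = FALSE]
    attr(s, "criterion") <- attr(cohort, "criterion")
    s
  })
  names(out) <- names(split_info$levels)
  low <- vapply(out, function(s) sum(s$case), integer(1)) < 10
  if (any(low)) {
    warn(sprintf("Stratum with < 10 cases on axis %s: %s.", axis,
                 paste(names(out)[low], collapse = ", ")))
  }
  structure(out, axis = axis, dropped = sum(!keep))
}

#' Check the minimum-events rule for external validation
#'
#' External validation of a binary outcome is conventionally considered
#' adequately precise with at least 100 events and 100 non-events; below
#' that the check returns a warning status carried into reports.
#'
#' @param cohort Analysis cohort.
#' @return List with `status` (`"pass"`/`"warn"`), `n_cases`,
#'   `n_noncases` and a human-readable `message`.
#' @export
check_min_events <- function(cohort) {
  n_cases <- sum(cohort$case)
  n_noncases <- sum(!cohort$case)
  ok <- n_cases >= 100 && n_noncases >= 100
  list(
    status = if (ok) "pass" else "warn",
    n_cases = n_cases,
    n_noncases = n_noncases,
    message = sprintf(
      "%d events and %d non-events%s",
      n_cases, n_noncases,
      if (ok) "" else " (below the 100/100 minimum recommended for validation)"
    )
  )
}

#' Read / write the participant-visit cohort CSV
#'
#' One row per participant-visit; header names follow the visit column
#' dictionary; missing values are empty strings. Units are fixed: cm
#' (waist), kg/m2 (BMI), mmHg (blood pressure), mmol/L (FPG), % (HbA1c).
#'
#' @param path CSV file path.
#' @return A tibble of visit rows.
#' @export
read_cohort <- function(path) {
  readr::read_csv(
    path, na = "", show_col_types = FALSE,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      visit_index = readr::col_integer(),
      sex = readr::col_character(),
      bp_medication = readr::col_character(),
      hypertension = readr::col_character(),
      family_history_dm = readr::col_character(),
      physical_activity = readr::col_integer(),
      residency = readr::col_character(),
      diabetes_medication = readr::col_character(),
      .default = readr::col_double()
    )
  )
}

#' @rdname read_cohort
#' @param data Visit-level tibble.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data[, intersect(visit_columns, names(data))], path, na = "")
  invisible(path)
}
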