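#' Configuration of the synthetic longitudinal cohort generator
#'
#' Bundles every generative parameter of the synthetic cohort: sample
#' size, covariate distributions, the true logistic risk model linking
#' covariates to screen-detected diabetes, the correlated FPG/HbA1c
#' latent, diagnosis-visit allocation, medication and missingness
#' rates. Defaults emulate the published structure of the validation
#' cohort the package targets: n = 937 participants over three visits,
#' 70% women, age truncated-normal (mean 52, sd 10, minimum 30, median
#' about 51), BMI log-normal with median 25 kg/m2, 56% rural dwellers,
#' about 14% prevalent undiagnosed diabetes by FPG and 26% by HbA1c,
#' and 40% missing family-history data.
#'
#' @param n_participants Number of participants (default 937).
#' @param seed Default RNG seed used by [generate_cohort()].
#' @param female_fraction Proportion of women (default 0.70).
#' @param age Truncated-normal parameters `mean`, `sd`, `min` (years).
#' @param bmi Log-normal parameters `meanlog`, `sdlog` (median
#'   `exp(meanlog)` kg/m2).
#' @param wc Waist-circumference regression on BMI and sex:
#'   `intercept_female`, `intercept_male`, `slope` (cm per BMI unit),
#'   residual `sd` (cm).
#' @param bp Blood-pressure and hypertension parameters (intercepts and
#'   age slopes for systolic/diastolic pressure, residual sds,
#'   self-report sensitivity and false-positive rate, treated fraction
#'   among reporters, background medication rate).
#' @param family_history `prevalence` of a positive family history and
#'   participant-level `missing_rate` (default 0.40).
#' @param physical_activity Probabilities of the ordinal activity
#'   categories 1 (low) to 3 (high).
#' @param rural_fraction Proportion of rural dwellers (default 0.56).
#' @param true_model Logistic coefficients of the latent risk model on
#'   centred age and waist circumference, clinical hypertension and
#'   female sex; `intercept` is calibrated so the FPG-criterion
#'   prevalence is about 0.14 at the default covariate distribution and
#'   `hba1c_shift` lifts the HbA1c-criterion prevalence to about 0.26.
#' @param glycaemia Correlation `rho` of the bivariate case-status
#'   latent, class-conditional normal parameters of each analyte,
#'   diagnostic thresholds (7 mmol/L, 6.5%) and truncation ranges.
#' @param visit_count Number of visits (fixed design: 3).
#' @param visit_diagnosis_probs Probabilities that a case is first
#'   diagnosable at visit 1, 2 or 3.
#' @param medication_rate Probability that a severe case (diagnosis
#'   glycaemia at or above `severe_fpg` / `severe_hba1c`) is on diabetes
#'   medication from diagnosis onward (these participants exercise the
#'   exclusion rule).
#' @param severe_fpg,severe_hba1c Severity thresholds for medication.
#' @param analyte_missing_rate Per visit-analyte MCAR missingness.
#' @return Object of class `t2d_sim_config`.
#' @export
sim_config <- function(n_participants = 937,
                       seed = 20051,
                       female_fraction = 0.70,
                       age = list(mean = 52, sd = 10, min = 30),
                       bmi = list(meanlog = log(25), sdlog = 0.22),
                       wc = list(intercept_female = 24, intercept_male = 28,
                                 slope = 2.4, sd = 6),
                       bp = list(sbp_intercept = 104, sbp_age_slope = 0.5,
                                 sbp_sd = 14, dbp_intercept = 62,
                                 dbp_age_slope = 0.22, dbp_sd = 9,
                                 report_sensitivity = 0.75,
                                 report_false_positive = 0.05,
                                 treated_fraction = 0.45,
                                 background_med = 0.02),
                       family_history = list(prevalence = 0.14,
                                             missing_rate = 0.40),
                       physical_activity = c(0.45, 0.35, 0.20),
                       rural_fraction = 0.56,
                       true_model = list(intercept = -2.53, age = 0.055,
                                         waist_circumference = 0.045,
                                         hypertension = 0.60, female = 0.25,
                                         center_age = 52, center_wc = 86,
                                         hba1c_shift = 0.88),
                       glycaemia = list(rho = 0.7,
                                        fpg_noncase = c(mean = 5.3, sd = 0.6),
                                        fpg_case = c(mean = 8.3, sd = 1.3),
                                        hba1c_noncase = c(mean = 5.6, sd = 0.4),
                                        hba1c_case = c(mean = 7.4, sd = 0.9),
                                        fpg_threshold = 7,
                                        hba1c_threshold = 6.5,
                                        fpg_range = c(2.5, 20),
                                        hba1c_range = c(3.5, 15)),
                       visit_count = 3,
                       visit_diagnosis_probs = c(0.80, 0.12, 0.08),
                       medication_rate = 0.05,
                       severe_fpg = 9, severe_hba1c = 8,
                       analyte_missing_rate = 0.02) {
  cfg <- list(
    n_participants = n_participants, seed = seed,
    female_fraction = female_fraction, age = age, bmi = bmi, wc = wc,
    bp = bp, family_history = family_history,
    physical_activity = physical_activity, rural_fraction = rural_fraction,
    true_model = true_model, glycaemia = glycaemia,
    visit_count = visit_count,
    visit_diagnosis_probs = visit_diagnosis_probs,
    medication_rate = medication_rate, severe_fpg = severe_fpg,
    severe_hba1c = severe_hba1c,
    analyte_missing_rate = analyte_missing_rate
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  probs <- c(
    female_fraction = cfg$female_fraction,
    family_history_prevalence = cfg$family_history$prevalence,
    family_history_missing = cfg$family_history$missing_rate,
    rural_fraction = cfg$rural_fraction,
    medication_rate = cfg$medication_rate,
    analyte_missing_rate = cfg$analyte_missing_rate,
    visit_diagnosis = cfg$visit_diagnosis_probs,
    activity = cfg$physical_activity
  )
  if (any(probs < 0 | probs > 1)) {
    abort("All probability parameters must lie in [0, 1].")
  }
  if (abs(sum(cfg$visit_diagnosis_probs) - 1) > 1e-8) {
    abort("visit_diagnosis_probs must sum to 1.")
  }
  if (abs(sum(cfg$physical_activity) - 1) > 1e-8) {
    abort("physical_activity probabilities must sum to 1.")
  }
  gl <- cfg$glycaemia
  if (gl$rho <= -1 || gl$rho >= 1) abort("glycaemia rho must lie in (-1, 1).")
  if (gl$fpg_threshold <= gl$fpg_range[1] ||
      gl$fpg_threshold >= gl$fpg_range[2] ||
      gl$hba1c_threshold <= gl$hba1c_range[1] ||
      gl$hba1c_threshold >= gl$hba1c_range[2]) {
    abort("Infeasible prevalence target: diagnostic threshold outside the latent analyte support.")
  }
  if (cfg$n_participants < 1) abort("n_participants must be positive.")
  structure(cfg, class = "t2d_sim_config")
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_sim_config()] returns a validated `t2d_sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- sim_config()
  merged <- utils::modifyList(unclass(base), raw)
  for (f in c("physical_activity", "visit_diagnosis_probs")) {
    merged[[f]] <- as.numeric(unlist(merged[[f]]))
  }
  for (f in c("fpg_noncase", "fpg_case", "hba1c_noncase", "hba1c_case")) {
    merged$glycaemia[[f]] <- stats::setNames(
      as.numeric(unlist(merged$glycaemia[[f]])), c("mean", "sd"))
  }
  for (f in c("fpg_range", "hba1c_range")) {
    merged$glycaemia[[f]] <- as.numeric(unlist(merged$glycaemia[[f]]))
  }
  validate_sim_config(merged)
}

#' @rdname read_sim_config
#' @param config A `t2d_sim_config`.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# baseline covariates for n participants (no RNG seeding here)
draw_covariates <- function(cfg, n) {
  female <- runif(n) < cfg$female_fraction
  age <- rtnorm(n, cfg$age$mean, cfg$age$sd, lower = cfg$age$min)
  bmi <- exp(rnorm(n, cfg$bmi$meanlog, cfg$bmi$sdlog))
  wc <- ifelse(female, cfg$wc$intercept_female, cfg$wc$intercept_male) +
    cfg$wc$slope * bmi + rnorm(n, 0, cfg$wc$sd)
  bp <- draw_bp(cfg, age, n)
  family_history <- runif(n) < cfg$family_history$prevalence
  activity <- sample.int(length(cfg$physical_activity), n, replace = TRUE,
                         prob = cfg$physical_activity)
  rural <- runif(n) < cfg$rural_fraction
  tibble(
    female = female, age = age, bmi = bmi, waist_circumference = wc,
    systolic_bp = bp$sbp, diastolic_bp = bp$dbp,
    hypertension_report = bp$report, bp_medication = bp$med,
    family_history_dm = family_history, physical_activity = activity,
    rural = rural
  )
}

draw_bp <- function(cfg, age, n) {
  bp <- cfg$bp
  sbp <- bp$sbp_intercept + bp$sbp_age_slope * age + rnorm(n, 0, bp$sbp_sd)
  dbp <- bp$dbp_intercept + bp$dbp_age_slope * age + rnorm(n, 0, bp$dbp_sd)
  measured <- sbp >= 140 | dbp >= 90
  report <- ifelse(measured, runif(n) < bp$report_sensitivity,
                   runif(n) < bp$report_false_positive)
  med <- ifelse(report, runif(n) < bp$treated_fraction,
                runif(n) < bp$background_med)
  list(sbp = sbp, dbp = dbp, report = report, med = med)
}

# clinical hypertension as the generator (and analysis) defines it
cov_hypertension <- function(cov) {
  cov$hypertension_report | cov$bp_medication |
    cov$systolic_bp >= 140 | cov$diastolic_bp >= 90
}

true_linear_predictor <- function(tm, cov) {
  tm$intercept +
    tm$age * (cov$age - tm$center_age) +
    tm$waist_circumference * (cov$waist_circumference - tm$center_wc) +
    tm$hypertension * cov_hypertension(cov) +
    tm$female * cov$female
}

#' Generate a seeded synthetic longitudinal cohort
#'
#' Draws baseline covariates, assigns screen-detected diabetes status
#' under both diagnostic criteria from the true logistic risk model via
#' a correlated bivariate latent (so the FPG and HbA1c case sets
#' overlap imperfectly, as observed in practice), allocates each case a
#' first-diagnosis visit, and emits one row per participant-visit with
#' class-conditional FPG and HbA1c values that respect the diagnostic
#' thresholds exactly. A configurable fraction of severe cases is
#' placed on diabetes medication from diagnosis onward, exercising the
#' exclusion rule. Output is byte-identical for a fixed seed.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return Visit-level tibble (`n_participants * visit_count` rows) in
#'   the cohort-CSV dialect, with attributes `true_model` (a
#'   `t2d_true_model`), `truth` (per-participant tibble of linear
#'   predictor, true probabilities, case status and diagnosis visit)
#'   and `config`.
#' @export
generate_cohort <- function(config = sim_config(), seed = config$seed) {
  cfg <- validate_sim_config(config)
  withr::with_seed(seed, {
    n <- cfg$n_participants
    tm <- cfg$true_model
    gl <- cfg$glycaemia
    cov <- draw_covariates(cfg, n)
    lp <- true_linear_predictor(tm, cov)
    p_fpg <- plogis(lp)
    p_hba1c <- plogis(lp + tm$hba1c_shift)

    # correlated bivariate latent -> case status under each criterion
    z1 <- rnorm(n)
    z2 <- gl$rho * z1 + sqrt(1 - gl$rho^2) * rnorm(n)
    case_fpg <- pnorm(z1) < p_fpg
    case_hba1c <- pnorm(z2) < p_hba1c
    any_case <- case_fpg | case_hba1c

    dx_visit <- rep(NA_integer_, n)
    dx_visit[any_case] <- sample.int(
      cfg$visit_count, sum(any_case), replace = TRUE,
      prob = cfg$visit_diagnosis_probs[seq_len(cfg$visit_count)]
    )

    visits <- vector("list", cfg$visit_count)
    fh_missing <- runif(n) < cfg$family_history$missing_rate
    bmi_t <- cov$bmi
    wc_t <- cov$waist_circumference
    report_t <- cov$hypertension_report
    med_t <- cov$bp_medication
    dx_fpg <- rep(NA_real_, n)
    dx_hba1c <- rep(NA_real_, n)
    on_dm_med <- rep(FALSE, n)

    for (v in seq_len(cfg$visit_count)) {
      age_v <- cov$age + 5 * (v - 1)
      if (v > 1) {
        bmi_t <- bmi_t + rnorm(n, 0, 0.8)
        wc_t <- cov$waist_circumference +
          cfg$wc$slope * (bmi_t - cov$bmi) + rnorm(n, 0, 2)
        bp_v <- draw_bp(cfg, age_v, n)
        report_t <- report_t | bp_v$report # self-report is sticky
        med_t <- med_t | bp_v$med
        sbp_v <- bp_v$sbp
        dbp_v <- bp_v$dbp
      } else {
        sbp_v <- cov$systolic_bp
        dbp_v <- cov$diastolic_bp
      }

      fpg_case_now <- case_fpg & !is.na(dx_visit) & v >= dx_visit
      hba1c_case_now <- case_hba1c & !is.na(dx_visit) & v >= dx_visit
      fpg_v <- draw_analyte(n, fpg_case_now, gl$fpg_case, gl$fpg_noncase,
                            gl$fpg_threshold, gl$fpg_range)
      hba1c_v <- draw_analyte(n, hba1c_case_now, gl$hba1c_case,
                              gl$hba1c_noncase, gl$hba1c_threshold,
                              gl$hba1c_range)

      at_dx <- !is.na(dx_visit) & dx_visit == v
      dx_fpg[at_dx] <- fpg_v[at_dx]
      dx_hba1c[at_dx] <- hba1c_v[at_dx]
      severe <- at_dx & ((fpg_case_now & fpg_v >= cfg$severe_fpg) |
                           (hba1c_case_now & hba1c_v >= cfg$severe_hba1c))
      on_dm_med <- on_dm_med | (severe & runif(n) < cfg$medication_rate)

      fpg_v[runif(n) < cfg$analyte_missing_rate] <- NA_real_
      hba1c_v[runif(n) < cfg$analyte_missing_rate] <- NA_real_

      visits[[v]] <- tibble(
        participant_id = sprintf("P%05d", seq_len(n)),
        visit_index = v,
        age = age_v,
        sex = ifelse(cov$female, "female", "male"),
        waist_circumference = wc_t,
        bmi = bmi_t,
        systolic_bp = sbp_v,
        diastolic_bp = dbp_v,
        bp_medication = lgl_to_yn(med_t),
        hypertension = lgl_to_yn(report_t),
        family_history_dm = ifelse(fh_missing, NA_character_,
                                   lgl_to_yn(cov$family_history_dm)),
        physical_activity = ifelse(runif(n) < 0.05,
                                   NA_integer_, cov$physical_activity),
        residency = ifelse(cov$rural, "rural", "urban"),
        diabetes_medication = lgl_to_yn(on_dm_med &
                                          !is.na(dx_visit) & v >= dx_visit),
        fpg = fpg_v,
        hba1c = hba1c_v
      )
    }

    out <- bind_rows(visits) %>% arrange(.data$participant_id, .data$visit_index)
    truth <- tibble(
      participant_id = sprintf("P%05d", seq_len(n)),
      lp = lp, p_fpg = p_fpg, p_hba1c = p_hba1c,
      case_fpg = case_fpg, case_hba1c = case_hba1c,
      diagnosis_visit = dx_visit, medicated = on_dm_med
    )
    structure(out,
              true_model = new_true_model(cfg),
              truth = truth, config = cfg, seed = seed,
              class = c("t2d_sim_cohort", class(out)))
  })
}

# class-conditional truncated-normal analyte values respecting the threshold
draw_analyte <- function(n, is_case, case_par, noncase_par, threshold, range) {
  u <- runif(n)
  out <- numeric(n)
  out[!is_case] <- qtnorm(u[!is_case], noncase_par[["mean"]],
                          noncase_par[["sd"]], range[1], threshold - 1e-9)
  out[is_case] <- qtnorm(u[is_case], case_par[["mean"]], case_par[["sd"]],
                         threshold, range[2])
  out
}

new_true_model <- function(cfg) {
  tm <- cfg$true_model
  structure(
    list(
      intercept = tm$intercept - tm$age * tm$center_age -
        tm$waist_circumference * tm$center_wc,
      coefficients = c(age = tm$age,
                       waist_circumference = tm$waist_circumference,
                       hypertension = tm$hypertension, female = tm$female),
      hba1c_shift = tm$hba1c_shift,
      centered = tm
    ),
    class = "t2d_true_model"
  )
}

#' True generative model of a synthetic cohort
#'
#' @param cohort A cohort from [generate_cohort()].
#' @return The `t2d_true_model` attribute (raw-scale logistic
#'   coefficients on age, waist circumference, clinical hypertension and
#'   female sex).
#' @export
true_model <- function(cohort) attr(cohort, "true_model")

#' @rdname true_model
#' @return `cohort_truth()`: per-participant tibble of the latent linear
#'   predictor, true probabilities under each criterion, case status and
#'   diagnosis visit.
#' @export
cohort_truth <- function(cohort) attr(cohort, "truth")

#' Express the true model as a score specification
#'
#' Emits the generator's logistic risk model in the declarative
#' score-spec format consumed by [score_cohort()], closing the loop for
#' parameter-recovery tests: scoring the generated cohort with this
#' spec reproduces the true probabilities.
#'
#' @param tm A `t2d_true_model` (see [true_model()]).
#' @param criterion `"fpg"` (default) or `"hba1c"` — the HbA1c variant
#'   adds the prevalence shift to the intercept.
#' @return A `t2d_score_spec` of logistic form.
#' @export
as_score_spec <- function(tm, criterion = c("fpg", "hba1c")) {
  criterion <- match.arg(criterion)
  shift <- if (criterion == "hba1c") tm$hba1c_shift else 0
  score_spec(
    name = paste0("TRUE_MODEL_", toupper(criterion)),
    form = "logistic",
    intercept = tm$intercept + shift,
    items = list(
      list(predictor = "age", kind = "linear_coefficient",
           coefficient = unname(tm$coefficients["age"])),
      list(predictor = "waist_circumference", kind = "linear_coefficient",
           coefficient = unname(tm$coefficients["waist_circumference"])),
      list(predictor = "hypertension", kind = "categorical_points",
           levels = list(yes = unname(tm$coefficients["hypertension"]),
                         no = 0)),
      list(predictor = "sex", kind = "categorical_points",
           levels = list(female = unname(tm$coefficients["female"]),
                         male = 0))
    ),
    probability_link = list(type = "direct_logistic"),
    hypertension_definition = "clinical",
    provisional = FALSE,
    source = "synthetic generator ground truth"
  )
}

#' Baseline cross-section of a synthetic cohort
#'
#' Visit-1 covariates joined with any-visit case status under the
#' chosen criterion — the population the true model parameterises, used
#' for parameter-recovery checks.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param criterion `"fpg"` or `"hba1c"`.
#' @return Tibble of baseline rows with a logical `case` column and
#'   derived `hypertension_clinical`.
#' @export
baseline_cross_section <- function(cohort, criterion = c("fpg", "hba1c")) {
  criterion <- match.arg(criterion)
  truth <- cohort_truth(cohort)
  if (is.null(truth)) abort("Cohort carries no truth attribute.")
  base <- dplyr::filter(as_tibble(cohort), .data$visit_index == 1L)
  base$hypertension_clinical <- derive_hypertension(base)
  case_col <- if (criterion == "fpg") "case_fpg" else "case_hba1c"
  dplyr::left_join(base,
                   dplyr::select(truth, "participant_id",
                                 case = dplyr::all_of(case_col)),
                   by = "participant_id")
}

#' Monte-Carlo implied population AUC of a true model
#'
#' Large-sample estimate of the C-statistic the true model attains on
#' its own population: covariates are drawn from the configuration,
#' outcomes from the model's probabilities, and concordance computed by
#' ranks.
#'
#' @param config A [sim_config()].
#' @param criterion `"fpg"` or `"hba1c"`.
#' @param n Monte-Carlo sample size.
#' @param seed RNG seed.
#' @return The implied AUC (single number).
#' @export
implied_auc <- function(config = sim_config(), criterion = c("fpg", "hba1c"),
                        n = 200000, seed = 1) {
  criterion <- match.arg(criterion)
  cfg <- validate_sim_config(config)
  withr::with_seed(seed, {
    cov <- draw_covariates(cfg, n)
    lp <- true_linear_predictor(cfg$true_model, cov)
    if (criterion == "hba1c") lp <- lp + cfg$true_model$hba1c_shift
    p <- plogis(lp)
    y <- runif(n) < p
    r <- rank(p)
    (mean(r[y]) - (sum(y) + 1) / 2) / sum(!y)
  })
}

#' Inject missing-completely-at-random values
#'
#' Masks each listed column independently at the given rate; the input
#' table is not modified in place.
#'
#' @param data A data frame.
#' @param rates Named list/vector of per-column missingness rates in
#'   [0, 1].
#' @param seed RNG seed.
#' @return The masked tibble.
#' @export
inject_missingness <- function(data, rates, seed = 1) {
  rates <- unlist(rates)
  if (any(rates < 0 | rates > 1)) abort("Missingness rates must lie in [0, 1].")
  bad <- setdiff(names(rates), names(data))
  if (length(bad) > 0) {
    abort(paste0("Unknown column(s): ", paste(bad, collapse = ", ")))
  }
  out <- as_tibble(data)
  withr::with_seed(seed, {
    for (cl in names(rates)) {
      mask <- runif(nrow(out)) < rates[[cl]]
      out[[cl]][mask] <- NA
    }
  })
  out
}

#' Extend a baseline cohort to three visits with incident conversion
#'
#' Takes single-visit (baseline) rows and simulates follow-up: at each
#' later visit, participants below both diagnostic thresholds convert
#' to cases with probability `incidence` (glycaemia redrawn above
#' threshold); a `medication_rate` fraction of converters is flagged on
#' diabetes medication from conversion onward. Ages advance five years
#' per visit. Baseline cases remain cases throughout.
#'
#' @param base Tibble of visit-1 rows.
#' @param incidence Per-visit conversion probability among at-risk
#'   noncases, in [0, 1].
#' @param medication_rate Probability a case is medicated from its
#'   diagnosis visit onward.
#' @param seed RNG seed.
#' @param glycaemia Class-conditional analyte parameters (defaults to
#'   `sim_config()$glycaemia`).
#' @param visit_count Total number of visits (default 3).
#' @return Visit-level tibble with `visit_count` rows per participant.
#' @export
make_longitudinal <- function(base, incidence, medication_rate = 0, seed = 1,
                              glycaemia = sim_config()$glycaemia,
                              visit_count = 3) {
  if (incidence < 0 || incidence > 1) abort("incidence must lie in [0, 1].")
  base <- as_tibble(base)
  n <- nrow(base)
  gl <- glycaemia
  withr::with_seed(seed, {
    case_fpg <- !is.na(base$fpg) & base$fpg >= gl$fpg_threshold
    case_hba1c <- !is.na(base$hba1c) & base$hba1c >= gl$hba1c_threshold
    is_case <- case_fpg | case_hba1c
    on_med <- yn_to_lgl(base$diabetes_medication)
    on_med[is.na(on_med)] <- FALSE
    on_med <- on_med | (is_case & runif(n) < medication_rate)
    rows <- list(dplyr::mutate(base, visit_index = 1L,
                               diabetes_medication = lgl_to_yn(on_med)))
    for (v in 2:visit_count) {
      at_risk <- !is_case
      convert <- at_risk & runif(n) < incidence
      # converters cross both thresholds; established cases keep their
      # criterion-specific status
      case_fpg <- case_fpg | convert
      case_hba1c <- case_hba1c | convert
      is_case <- case_fpg | case_hba1c
      on_med <- on_med | (convert & runif(n) < medication_rate)
      fpg_v <- draw_analyte(n, case_fpg, gl$fpg_case, gl$fpg_noncase,
                            gl$fpg_threshold, gl$fpg_range)
      hba1c_v <- draw_analyte(n, case_hba1c, gl$hba1c_case, gl$hba1c_noncase,
                              gl$hba1c_threshold, gl$hba1c_range)
      rows[[v]] <- base %>%
        mutate(visit_index = as.integer(v), age = .data$age + 5 * (v - 1),
               fpg = fpg_v, hba1c = hba1c_v,
               diabetes_medication = lgl_to_yn(on_med))
    }
    bind_rows(rows) %>% arrange(.data$participant_id, .data$visit_index)
  })
}
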