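#' Run the full external-validation grid
#'
#' For every score model and diagnostic criterion: assemble the
#' analysis dataset (first-diagnosis visit for cases, baseline for
#' noncases, medication exclusions), apply the model-specific
#' complete-case filter, check the 100-events rule, score, compute
#' discrimination (C-statistic with DeLong CI, ROC-derived Youden and
#' top-left thresholds, sensitivity/specificity) and calibration (E/O
#' with Poisson CI, Brier, Yates slope, Hosmer-Lemeshow) for the
#' original model, recalibrate by intercept update, recompute
#' calibration for the recalibrated model, and evaluate the subgroup
#' grid (sex, median age, BMI 25, residency) on recalibrated
#' probabilities. Discrimination is identical before and after
#' recalibration because the intercept shift is strictly monotone.
#' Failures are captured per cell; remaining cells are still computed.
#'
#' @param data Visit-level cohort tibble (or path handled by
#'   [read_cohort()] upstream).
#' @param score_specs Named list of `t2d_score_spec` objects (default
#'   the four bundled models).
#' @param criteria Diagnostic criteria to run (default both).
#' @param recalibrate `"one_step"` (default) or `"iterated"`.
#' @param subgroups Subgroup axes (default all four; `NULL` for none).
#' @param hl_groups Hosmer-Lemeshow group count (default 10).
#' @param subgroup_probabilities Evaluate subgroups on
#'   `"recalibrated"` (default) or `"original"` probabilities.
#' @param subgroup_recalibration `"overall"` (default; the whole-cohort
#'   correction factor applied within strata) or `"per_stratum"`.
#' @param conf_level Confidence level for intervals.
#' @return Object of class `t2d_validation`: list of tibbles `cells`
#'   (one row per model x criterion x original/recalibrated),
#'   `subgroups`, `errors`, `warnings` and `meta`.
#' @export
run_validation <- function(data,
                           score_specs = bundled_score_specs(),
                           criteria = c("fpg", "hba1c"),
                           recalibrate = c("one_step", "iterated"),
                           subgroups = c("sex", "age_median", "bmi_25",
                                         "residency"),
                           hl_groups = 10,
                           subgroup_probabilities = c("recalibrated",
                                                      "original"),
                           subgroup_recalibration = c("overall",
                                                      "per_stratum"),
                           conf_level = 0.95) {
  recalibrate <- match.arg(recalibrate)
  subgroup_probabilities <- match.arg(subgroup_probabilities)
  subgroup_recalibration <- match.arg(subgroup_recalibration)
  if (length(score_specs) == 0) abort("At least one score spec required.")
  if (is.null(names(score_specs))) {
    names(score_specs) <- vapply(score_specs, `[[`, character(1), "name")
  }

  cells <- list()
  subs <- list()
  errs <- list()
  warns <- list()

  for (crit in criteria) {
    assembled <- withCallingHandlers(
      assemble_analysis_dataset(data, crit),
      warning = function(w) {
        warns[[length(warns) + 1]] <<- tibble(
          model = NA_character_, criterion = crit, stage = "assemble",
          message = conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage")
    )
    for (nm in names(score_specs)) {
      spec <- score_specs[[nm]]
      res <- tryCatch(
        withCallingHandlers(
          validate_one(assembled, spec, crit, recalibrate, subgroups,
                       hl_groups, subgroup_probabilities,
                       subgroup_recalibration, conf_level),
          warning = function(w) {
            warns[[length(warns) + 1]] <<- tibble(
              model = nm, criterion = crit, stage = "cell",
              message = conditionMessage(w))
            invokeRestart("muffleWarning")
          }
        ),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        errs[[length(errs) + 1]] <- tibble(
          model = nm, criterion = crit, stage = "cell",
          message = conditionMessage(res))
      } else {
        cells[[length(cells) + 1]] <- res$cells
        if (!is.null(res$subgroups)) subs[[length(subs) + 1]] <- res$subgroups
        if (res$min_events$status == "warn") {
          warns[[length(warns) + 1]] <- tibble(
            model = nm, criterion = crit, stage = "min_events",
            message = res$min_events$message)
        }
      }
    }
  }

  empty_log <- tibble(model = character(), criterion = character(),
                      stage = character(), message = character())
  structure(
    list(
      cells = if (length(cells)) bind_rows(cells) else tibble(),
      subgroups = if (length(subs)) bind_rows(subs) else tibble(),
      errors = if (length(errs)) bind_rows(errs) else empty_log,
      warnings = if (length(warns)) bind_rows(warns) else empty_log,
      meta = list(
        models = names(score_specs), criteria = criteria,
        recalibrate = recalibrate, subgroup_axes = subgroups,
        hl_groups = hl_groups,
        subgroup_probabilities = subgroup_probabilities,
        subgroup_recalibration = subgroup_recalibration,
        conf_level = conf_level
      )
    ),
    class = "t2d_validation"
  )
}

# one model x criterion cell pair (original + recalibrated) + subgroups
validate_one <- function(assembled, spec, crit, recalibrate, subgroups,
                         hl_groups, subgroup_probabilities,
                         subgroup_recalibration, conf_level) {
  cc <- complete_case_filter(assembled, spec)
  me <- check_min_events(cc)
  scored <- score_cohort(cc, spec)
  y <- scored$case
  p0 <- scored$probability

  recal <- apply_recalibration(p0, labels = y, mode = recalibrate)
  p1 <- recal$probabilities_after

  cs <- c_statistic(p0[y], p0[!y], conf_level)
  cell_row <- function(state, p, factor) {
    roc <- roc_curve(p, y)
    yt <- youden_threshold(roc)
    tl <- top_left_threshold(roc)
    eor <- eo_ratio(p, y, conf_level)
    hl <- hosmer_lemeshow(p, y, g = hl_groups)
    tibble(
      model = spec$name, criterion = crit, state = state,
      n = length(y), cases = sum(y),
      expected = eor$expected, eo = eor$ratio,
      eo_low = eor$ci_low, eo_high = eor$ci_high,
      brier = brier_score(p, y), yates = yates_slope(p, y),
      c = cs$c, c_se = cs$se, c_low = cs$ci_low, c_high = cs$ci_high,
      threshold = yt$threshold, sensitivity = yt$sensitivity,
      specificity = yt$specificity, youden_j = yt$j,
      threshold_top_left = tl$threshold,
      hl_chi2 = hl$chi2, hl_df = hl$df, hl_p = hl$p_value,
      correction_factor = factor,
      min_events = me$status
    )
  }
  cells <- bind_rows(
    cell_row("original", p0, NA_real_),
    cell_row("recalibrated", p1, recal$correction_factor)
  )

  sub_rows <- NULL
  if (length(subgroups) > 0) {
    p_sub <- if (subgroup_probabilities == "recalibrated") p1 else p0
    sub_rows <- purrr::map(subgroups, function(ax) {
      strata <- suppressWarnings(stratify(scored, ax))
      two <- purrr::imap(strata, function(s, lab) {
        idx <- match(s$participant_id, scored$participant_id)
        ps <- p_sub[idx]
        ys <- s$case
        if (sum(ys) == 0 || sum(!ys) == 0) {
          abort(sprintf("Empty class in stratum %s of axis %s.", lab, ax))
        }
        if (subgroup_recalibration == "per_stratum" &&
            subgroup_probabilities == "recalibrated") {
          ps <- apply_recalibration(p0[idx], labels = ys,
                                    mode = "one_step")$probabilities_after
        }
        eor <- eo_ratio(ps, ys, conf_level)
        csx <- c_statistic(ps[ys], ps[!ys], conf_level)
        list(
          row = tibble(
            model = spec$name, criterion = crit, axis = ax, stratum = lab,
            n = nrow(s), cases = sum(ys),
            eo = eor$ratio, eo_low = eor$ci_low, eo_high = eor$ci_high,
            c = csx$c, c_low = csx$ci_low, c_high = csx$ci_high,
            low_cases = sum(ys) < 10
          ),
          cs = csx
        )
      })
      cmp <- compare_c_independent(two[[1]]$cs, two[[2]]$cs)
      bind_rows(two[[1]]$row, two[[2]]$row) %>%
        mutate(p_compare = cmp$p_value)
    }) %>% bind_rows()
  }

  list(cells = cells, subgroups = sub_rows, min_events = me)
}

#' @export
print.t2d_validation <- function(x, ...) {
  cat(sprintf(
    "<t2d_validation> %d cells (%d models x %d criteria x 2 states), %d subgroup rows\n",
    nrow(x$cells), length(x$meta$models), length(x$meta$criteria),
    nrow(x$subgroups)))
  if (nrow(x$errors) > 0) {
    cat(sprintf("  %d cell(s) failed; see $errors\n", nrow(x$errors)))
  }
  if (nrow(x$warnings) > 0) {
    cat(sprintf("  %d warning(s); see $warnings\n", nrow(x$warnings)))
  }
  if (nrow(x$cells) > 0) {
    brief <- x$cells %>%
      dplyr::filter(.data$state == "original") %>%
      dplyr::transmute(
        .data$model, .data$criterion, .data$n, .data$cases,
        c = sprintf("%.2f [%.2f-%.2f]", .data$c, .data$c_low, .data$c_high),
        eo_original = round(.data$eo, 2)
      )
    print(as.data.frame(brief), row.names = FALSE)
  }
  invisible(x)
}
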