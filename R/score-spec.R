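score_kinds <- c("categorical_points", "threshold_points", "linear_coefficient")

allowed_predictors <- c(
  "age", "sex", "waist_circumference", "bmi", "systolic_bp", "diastolic_bp",
  "bp_medication", "hypertension", "family_history_dm", "physical_activity",
  "residency"
)

#' Construct a score specification programmatically
#'
#' A score specification declaratively encodes one risk model: its
#' items (predictor, categorisation and points or coefficients), its
#' form (`"points"` for additive point scores, `"logistic"` for a linear
#' predictor with intercept) and the link mapping the total score to a
#' probability of prevalent undiagnosed diabetes. Point scores carry a
#' `score_logistic` link `p = plogis(a + b * s)`; logistic scores use the
#' `direct_logistic` link `p = plogis(s)`.
#'
#' Item kinds:
#' * `categorical_points`: `cut_points` (strictly increasing, intervals
#'   lower-inclusive `[lo, hi)`) with `values` one longer than
#'   `cut_points`; or, for discrete predictors, a named `levels` map.
#'   `sex_specific` may override `cut_points` per sex.
#' * `threshold_points`: a single `cut_point` with `values = c(below,
#'   at_or_above)`.
#' * `linear_coefficient`: `coefficient` multiplying a numeric predictor.
#'
#' @param name Model name (e.g. `"ADRS"`).
#' @param form `"points"` or `"logistic"`.
#' @param items List of item lists as described above.
#' @param probability_link List with `type` (`"direct_logistic"` or
#'   `"score_logistic"`) and, for the latter, parameters `a` and `b`.
#' @param intercept Intercept of a logistic-form score.
#' @param hypertension_definition `"clinical"` (self-report, medication or
#'   measured BP >= 140/90) or `"medication_only"`.
#' @param provisional Logical flag: coefficients transcribed or
#'   constructed provisionally rather than taken from a deposited source.
#' @param source Free-text citation of the primary publication.
#' @return A validated object of class `t2d_score_spec`.
#' @export
score_spec <- function(name, form, items, probability_link = NULL,
                       intercept = NULL,
                       hypertension_definition = c("clinical", "medication_only"),
                       provisional = FALSE, source = NULL) {
  spec <- list(
    name = name, form = form, items = items,
    probability_link = probability_link %||% list(type = "direct_logistic"),
    intercept = intercept,
    hypertension_definition = match.arg(hypertension_definition),
    provisional = isTRUE(provisional), source = source
  )
  validate_score_spec(spec)
}

#' Validate a score specification
#'
#' Checks structural and numeric constraints (known predictors, strictly
#' increasing cut points, one value per interval, link parameters) and
#' reports violations with field paths.
#'
#' @param spec A raw spec list.
#' @return The spec with class `t2d_score_spec`.
#' @export
validate_score_spec <- function(spec) {
  problems <- character()
  note <- function(path, msg) {
    problems <<- c(problems, sprintf("%s: %s", path, msg))
  }
  if (!is.character(spec$name) || length(spec$name) != 1) {
    note("name", "must be a single string")
  }
  if (!identical(spec$form, "points") && !identical(spec$form, "logistic")) {
    note("form", "must be 'points' or 'logistic'")
  }
  if (identical(spec$form, "logistic") && !is.numeric(spec$intercept)) {
    note("intercept", "required for logistic form")
  }
  link <- spec$probability_link
  if (is.null(link$type) ||
      !link$type %in% c("direct_logistic", "score_logistic")) {
    note("probability_link.type", "must be 'direct_logistic' or 'score_logistic'")
  } else if (link$type == "score_logistic" &&
             (!is.numeric(link$a) || !is.numeric(link$b))) {
    note("probability_link", "score_logistic link requires numeric 'a' and 'b'")
  }
  if (!is.list(spec$items) || length(spec$items) == 0) {
    note("items", "at least one item required")
  } else {
    for (i in seq_along(spec$items)) {
      it <- spec$items[[i]]
      path <- sprintf("items[%d]", i)
      if (is.null(it$predictor) || !it$predictor %in% allowed_predictors) {
        note(paste0(path, ".predictor"),
             sprintf("unknown predictor '%s'", it$predictor %||% "<missing>"))
        next
      }
      if (is.null(it$kind) || !it$kind %in% score_kinds) {
        note(paste0(path, ".kind"),
             sprintf("unknown kind '%s'", it$kind %||% "<missing>"))
        next
      }
      if (it$kind == "categorical_points") {
        if (!is.null(it$levels)) {
          if (length(it$levels) == 0 || is.null(names(it$levels))) {
            note(paste0(path, ".levels"), "must be a non-empty named map")
          }
        } else {
          cp <- it$cut_points
          if (is.null(cp) || length(cp) < 1 || anyNA(cp) ||
              is.unsorted(cp, strictly = TRUE)) {
            note(paste0(path, ".cut_points"),
                 "must be strictly increasing (overlapping or unordered bounds)")
          }
          if (is.null(it$values) ||
              length(it$values) != length(cp %||% numeric()) + 1) {
            note(paste0(path, ".values"),
                 "one value per interval required (length(cut_points) + 1)")
          }
          if (!is.null(it$sex_specific)) {
            for (sx in names(it$sex_specific)) {
              scp <- it$sex_specific[[sx]]$cut_points
              if (!sx %in% c("male", "female")) {
                note(paste0(path, ".sex_specific"),
                     sprintf("unknown sex '%s'", sx))
              } else if (is.null(scp) ||
                         length(scp) != length(cp %||% numeric()) ||
                         is.unsorted(scp, strictly = TRUE)) {
                note(paste0(path, ".sex_specific.", sx, ".cut_points"),
                     "must match base cut_points in length and be strictly increasing")
              }
            }
          }
        }
      } else if (it$kind == "threshold_points") {
        if (!is.numeric(it$cut_point) || length(it$cut_point) != 1) {
          note(paste0(path, ".cut_point"), "single numeric threshold required")
        }
        if (is.null(it$values) || length(it$values) != 2) {
          note(paste0(path, ".values"), "values = c(below, at_or_above) required")
        }
      } else if (it$kind == "linear_coefficient") {
        if (!is.numeric(it$coefficient) || length(it$coefficient) != 1) {
          note(paste0(path, ".coefficient"), "single numeric coefficient required")
        }
      }
    }
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid score spec", if (!is.null(spec$name)) paste0(" '", spec$name, "'"),
                 ":\n- ", paste(problems, collapse = "\n- ")))
  }
  class(spec) <- "t2d_score_spec"
  spec
}

#' Load a score specification from JSON or YAML
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`,
#'   `.yml`).
#' @return A validated `t2d_score_spec`.
#' @export
load_score_spec <- function(path) {
  if (!file.exists(path)) abort(sprintf("Score spec file not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  }
  raw$items <- lapply(raw$items, function(it) {
    for (f in c("cut_points", "values")) {
      if (!is.null(it[[f]])) it[[f]] <- as.numeric(unlist(it[[f]]))
    }
    if (!is.null(it$levels)) it$levels <- lapply(it$levels, as.numeric)
    if (!is.null(it$sex_specific)) {
      it$sex_specific <- lapply(it$sex_specific, function(s) {
        s$cut_points <- as.numeric(unlist(s$cut_points))
        s
      })
    }
    it
  })
  validate_score_spec(raw)
}

#' Write a score specification to JSON or YAML
#'
#' The serialisation round-trips: [load_score_spec()] on the written
#' file reproduces an identical spec.
#'
#' @param spec A `t2d_score_spec`.
#' @param path Output file path (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
write_score_spec <- function(spec, path) {
  x <- unclass(spec)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

#' Bundled risk-score specifications
#'
#' Loads the four risk models shipped with the package: the African
#' Diabetes Risk Score (ADRS; age, waist circumference, hypertension),
#' the Simplified FINDRISC (age, BMI, waist, blood-pressure medication,
#' family history), the ADA risk test (age, sex, family history,
#' hypertension, BMI, physical activity) and the Indian Diabetes Risk
#' Score (age, waist, physical activity, family history). All bundled
#' files are flagged provisional: the ADRS coefficients are unpublished
#' and the remaining point tables and score-to-probability links are
#' transcriptions from the cited primary publications.
#'
#' @param names Subset of model names to load (default all four).
#' @return Named list of `t2d_score_spec` objects.
#' @export
bundled_score_specs <- function(names = c("ADRS", "SIMPLIFIED_FINDRISC",
                                          "ADA", "IRS")) {
  files <- c(
    ADRS = "adrs.json", SIMPLIFIED_FINDRISC = "findrisc_simplified.json",
    ADA = "ada.json", IRS = "irs.json"
  )
  names <- match.arg(names, several.ok = TRUE)
  out <- lapply(names, function(nm) {
    load_score_spec(system.file("extdata", "scores", files[[nm]],
                                package = "t2dval", mustWork = TRUE))
  })
  stats::setNames(out, names)
}

# cohort columns a spec needs, resolving the hypertension definition
required_columns <- function(spec) {
  preds <- vapply(spec$items, function(it) it$predictor, character(1))
  cols <- character()
  for (p in unique(preds)) {
    cols <- c(cols, switch(p,
      hypertension = if (identical(spec$hypertension_definition,
                                   "medication_only")) {
        "bp_medication"
      } else "hypertension_clinical",
      p
    ))
  }
  # sex-specific cut points additionally require sex
  sex_needed <- any(vapply(spec$items,
                           function(it) !is.null(it$sex_specific), logical(1)))
  if (sex_needed) cols <- union(cols, "sex")
  unique(cols)
}

#' @export
print.t2d_score_spec <- function(x, ...) {
  cat(sprintf("<t2d_score_spec> %s (%s form, %d items, link %s%s)\n",
              x$name, x$form, length(x$items), x$probability_link$type,
              if (isTRUE(x$provisional)) ", provisional" else ""))
  for (it in x$items) cat(sprintf("  - %s [%s]\n", it$predictor, it$kind))
  invisible(x)
}
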