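#' Evaluate a risk score on analysis records
#'
#' Computes the raw score (total points, or linear predictor for
#' logistic-form models) for each record. Evaluation is deterministic
#' and depends only on the predictors the spec names; a record missing a
#' required predictor yields `NA` — a not-applicable signal, never a
#' default value — so run [complete_case_filter()] first for a fully
#' scored cohort.
#'
#' @param spec A `t2d_score_spec`.
#' @param data Data frame of analysis records.
#' @return Numeric vector of raw scores, one per row.
#' @export
evaluate_score <- function(spec, data) {
  data <- as_tibble(data)
  n <- nrow(data)
  total <- rep(if (identical(spec$form, "logistic")) spec$intercept else 0, n)
  for (i in seq_along(spec$items)) {
    it <- spec$items[[i]]
    x <- item_values(spec, it, data)
    contrib <- item_contribution(it, x, data)
    total <- total + contrib
  }
  as.numeric(total)
}

# resolve the predictor column for an item (hypertension definition aware)
item_values <- function(spec, it, data) {
  col <- if (identical(it$predictor, "hypertension")) {
    if (identical(spec$hypertension_definition, "medication_only")) {
      "bp_medication"
    } else if ("hypertension_clinical" %in% names(data)) {
      "hypertension_clinical"
    } else {
      return(derive_hypertension(data))
    }
  } else {
    it$predictor
  }
  if (!col %in% names(data)) {
    abort(sprintf("Column `%s` (predictor %s) not found in data.",
                  col, it$predictor))
  }
  data[[col]]
}

item_contribution <- function(it, x, data) {
  if (it$kind == "linear_coefficient") {
    if (!is.numeric(x)) x <- as.numeric(yn_to_lgl(x))
    return(it$coefficient * x)
  }
  if (it$kind == "threshold_points") {
    if (!is.numeric(x)) x <- as.numeric(yn_to_lgl(x))
    return(ifelse(is.na(x), NA_real_,
                  ifelse(x >= it$cut_point, it$values[2], it$values[1])))
  }
  # categorical_points
  if (!is.null(it$levels)) {
    key <- if (is.logical(x)) lgl_to_yn(x) else as.character(x)
    vals <- unlist(it$levels)
    out <- unname(vals[key])
    unknown <- !is.na(key) & !key %in% names(vals)
    if (any(unknown)) {
      abort(sprintf("Predictor %s has level(s) %s not covered by the spec.",
                    it$predictor,
                    paste(unique(key[unknown]), collapse = ", ")))
    }
    return(as.numeric(out))
  }
  x <- as.numeric(x)
  if (is.null(it$sex_specific)) {
    idx <- findInterval(x, it$cut_points) + 1L # [lo, hi) lower-inclusive
    return(it$values[idx])
  }
  sex <- data$sex
  out <- rep(NA_real_, length(x))
  for (sx in c("male", "female")) {
    cp <- it$sex_specific[[sx]]$cut_points %||% it$cut_points
    sel <- !is.na(sex) & sex == sx
    out[sel] <- it$values[findInterval(x[sel], cp) + 1L]
  }
  out[is.na(sex)] <- NA_real_
  out
}

#' Map a raw score to a probability of prevalent undiagnosed diabetes
#'
#' Logistic-form scores use the direct logistic link
#' `p = plogis(raw_score)`; point scores use the spec's score-logistic
#' link `p = plogis(a + b * raw_score)`. Both links are strictly
#' increasing in the raw score.
#'
#' @param spec A `t2d_score_spec`.
#' @param raw_score Numeric vector from [evaluate_score()].
#' @return Probabilities strictly inside (0, 1).
#' @export
score_to_probability <- function(spec, raw_score) {
  link <- spec$probability_link
  if (identical(link$type, "direct_logistic")) {
    return(plogis(raw_score))
  }
  if (!is.numeric(link$b) || link$b <= 0) {
    abort(sprintf("Score spec %s: score_logistic slope b must be > 0.",
                  spec$name))
  }
  plogis(link$a + link$b * raw_score)
}

#' Score every record of an analysis cohort
#'
#' Order-preserving: one output row per input record, with the raw score
#' and predicted probability appended. Apply [complete_case_filter()]
#' for the same spec first; otherwise rows with missing predictors carry
#' `NA` scores.
#'
#' @param cohort Analysis cohort (tibble with a `case` column).
#' @param spec A `t2d_score_spec`.
#' @return The cohort tibble with added `raw_score` and `probability`
#'   columns; attribute `model` holds the spec name.
#' @export
score_cohort <- function(cohort, spec) {
  out <- as_tibble(cohort)
  out$raw_score <- evaluate_score(spec, out)
  out$probability <- score_to_probability(spec, out$raw_score)
  if (anyNA(out$raw_score)) {
    bad <- out$participant_id[is.na(out$raw_score)]
    warn(sprintf(
      "%d record(s) could not be scored by %s (missing predictors): %s%s",
      length(bad), spec$name, paste(head(bad, 5), collapse = ", "),
      if (length(bad) > 5) ", ..." else ""
    ))
  }
  attr(out, "model") <- spec$name
  attr(out, "criterion") <- attr(cohort, "criterion")
  out
}
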