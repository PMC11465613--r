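#' Concordance (C) statistic with DeLong confidence interval
#'
#' The C-statistic is the probability that a randomly chosen case
#' carries a higher predicted risk than a randomly chosen noncase, with
#' ties counted half: `c = (#concordant + 0.5 #tied) / (m * n)`. The
#' standard error uses the nonparametric structural-components (DeLong)
#' estimator computed from midrank placements, and the normal-theory
#' confidence interval is truncated to [0, 1].
#'
#' @param probs_cases Predicted probabilities (or any risk score) of the
#'   cases.
#' @param probs_noncases Predicted probabilities of the noncases.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `t2d_cstat`: list with `c`, `se`, `ci_low`,
#'   `ci_high`, `n_cases`, `n_noncases`, `conf_level`.
#' @examples
#' c_statistic(c(0.8, 0.4), c(0.3, 0.5, 0.2))$c # 5/6
#' @export
c_statistic <- function(probs_cases, probs_noncases, conf_level = 0.95) {
  m <- length(probs_cases)
  n <- length(probs_noncases)
  if (m == 0 || n == 0) abort("Both case and noncase groups must be non-empty.")
  if (anyNA(probs_cases) || anyNA(probs_noncases)) {
    abort("Probabilities contain missing values.")
  }
  r_all <- rank(c(probs_cases, probs_noncases))
  r_cases <- rank(probs_cases)
  r_non <- rank(probs_noncases)
  # midrank placements (Sun & Xu): V10_i = P(noncase < case_i) + 0.5 ties
  v10 <- (r_all[seq_len(m)] - r_cases) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_non) / m
  cstat <- mean(v10)
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(
      c = cstat, se = se,
      ci_low = max(0, cstat - z * se), ci_high = min(1, cstat + z * se),
      n_cases = m, n_noncases = n, conf_level = conf_level
    ),
    class = "t2d_cstat"
  )
}

#' @export
print.t2d_cstat <- function(x, ...) {
  cat(sprintf("C-statistic %.3f [%.0f%% CI %.3f-%.3f] (%d cases, %d noncases)\n",
              x$c, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$n_cases, x$n_noncases))
  invisible(x)
}

#' Receiver operating characteristic curve
#'
#' One point per distinct probability value plus the all-negative
#' endpoint; the classification rule is positive iff
#' `probability >= threshold`. The trapezoidal area under the returned
#' polyline equals the C-statistic (ties handled by midranks) to
#' numerical precision.
#'
#' @param probs Predicted probabilities.
#' @param labels Case indicators (logical, 0/1 or yes/no).
#' @return Tibble of class `t2d_roc` with columns `threshold`,
#'   `sensitivity`, `specificity`; attribute `auc` holds the trapezoidal
#'   area.
#' @export
roc_curve <- function(probs, labels) {
  y <- as_case(labels)
  if (length(probs) != length(y)) abort("probs and labels differ in length.")
  if (all(y) || !any(y)) abort("Labels must contain both classes.")
  thr <- c(Inf, sort(unique(probs), decreasing = TRUE))
  m <- sum(y)
  n <- sum(!y)
  sens <- vapply(thr, function(t) sum(probs[y] >= t) / m, numeric(1))
  spec <- vapply(thr, function(t) sum(probs[!y] < t) / n, numeric(1))
  out <- tibble(threshold = thr, sensitivity = sens, specificity = spec)
  x <- 1 - out$specificity
  auc <- sum(diff(x) * (head(out$sensitivity, -1) + tail(out$sensitivity, -1)) / 2)
  structure(out, auc = auc, class = c("t2d_roc", class(out)))
}

#' Optimal threshold by the Youden index
#'
#' Maximises `J = sensitivity + specificity - 1` over the observed
#' thresholds of a ROC curve; ties resolve to the lowest threshold. J
#' ranges from 0 (complete overlap of the two populations) to 1
#' (complete separation).
#'
#' @param roc A `t2d_roc` from [roc_curve()].
#' @return One-row tibble: `method`, `threshold`, `sensitivity` and
#'   `specificity` (percent), `j`.
#' @export
youden_threshold <- function(roc) {
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j == max(j))
  pick <- best[which.min(roc$threshold[best])]
  tibble(
    method = "youden", threshold = roc$threshold[pick],
    sensitivity = 100 * roc$sensitivity[pick],
    specificity = 100 * roc$specificity[pick],
    j = j[pick]
  )
}

#' Optimal threshold by the top-left point
#'
#' Minimises the Euclidean distance to the ideal (sensitivity 1,
#' specificity 1) corner of ROC space; ties resolve to the lowest
#' threshold.
#'
#' @param roc A `t2d_roc` from [roc_curve()].
#' @return One-row tibble: `method`, `threshold`, `sensitivity` and
#'   `specificity` (percent), `j` at the chosen point, and `distance`.
#' @export
top_left_threshold <- function(roc) {
  d <- sqrt((1 - roc$sensitivity)^2 + (1 - roc$specificity)^2)
  best <- which(d == min(d))
  pick <- best[which.min(roc$threshold[best])]
  tibble(
    method = "top_left", threshold = roc$threshold[pick],
    sensitivity = 100 * roc$sensitivity[pick],
    specificity = 100 * roc$specificity[pick],
    j = roc$sensitivity[pick] + roc$specificity[pick] - 1,
    distance = d[pick]
  )
}

#' Sensitivity and specificity at a fixed threshold
#'
#' Positive iff `probability >= threshold`; percentages reported to one
#' decimal, matching conventional reporting precision.
#'
#' @param probs Predicted probabilities.
#' @param labels Case indicators.
#' @param threshold Classification threshold in [0, 1].
#' @return Named numeric vector `c(sensitivity, specificity)` in
#'   percent.
#' @export
sens_spec_at <- function(probs, labels, threshold) {
  y <- as_case(labels)
  if (!any(y) || all(y)) abort("Labels must contain both classes.")
  pos <- probs >= threshold
  c(
    sensitivity = round(100 * sum(pos & y) / sum(y), 1),
    specificity = round(100 * sum(!pos & !y) / sum(!y), 1)
  )
}

#' Compare C-statistics between independent subgroups
#'
#' Two-sided z-test for C-statistics estimated on disjoint strata:
#' `z = (c_a - c_b) / sqrt(se_a^2 + se_b^2)`. If both standard errors
#' are zero and the estimates coincide, p = 1 by convention.
#'
#' @param a,b `t2d_cstat` results computed on disjoint subgroups.
#' @return List with `z` and `p_value`.
#' @export
compare_c_independent <- function(a, b) {
  se <- sqrt(a$se^2 + b$se^2)
  if (se == 0) {
    if (a$c == b$c) return(list(z = 0, p_value = 1))
    abort("Zero standard errors with unequal C-statistics.")
  }
  z <- (a$c - b$c) / se
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Qualitative interpretation of a C-statistic
#'
#' Conventional bands, lower-inclusive: below 0.7 poor, 0.7-0.8
#' acceptable, 0.8-0.9 good, 0.9 and above excellent.
#'
#' @param c C-statistic(s) in [0, 1].
#' @return Character vector of band labels.
#' @examples
#' interpret_c(c(0.69, 0.77, 0.85))
#' @export
interpret_c <- function(c) {
  if (any(c < 0 | c > 1)) abort("C-statistic must lie in [0, 1].")
  cut(c, breaks = c(-Inf, 0.7, 0.8, 0.9, Inf), right = FALSE,
      labels = c("poor", "acceptable", "good", "excellent")) |>
    as.character()
}
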