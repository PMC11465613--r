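#' Brier score
#'
#' Mean squared difference between predicted probability and binary
#' outcome. Under the standard convention implemented here, 0 is a
#' perfect prediction and larger values are worse (bounded by 1).
#'
#' @param probs Predicted probabilities in [0, 1].
#' @param labels Case indicators.
#' @return A single number in [0, 1].
#' @examples
#' brier_score(c(0.8, 0.4), c(1, 0)) # 0.10
#' @export
brier_score <- function(probs, labels) {
  y <- as_case(labels)
  check_probs(probs)
  if (length(probs) == 0) abort("Empty input.")
  if (length(probs) != length(y)) abort("probs and labels differ in length.")
  mean((probs - y)^2)
}

#' Yates (discrimination) slope
#'
#' Difference between the mean predicted probability of cases and of
#' noncases; higher values indicate better separation.
#'
#' @inheritParams brier_score
#' @return A single number in [-1, 1].
#' @examples
#' yates_slope(c(0.8, 0.4), c(1, 0)) # 0.4
#' @export
yates_slope <- function(probs, labels) {
  y <- as_case(labels)
  check_probs(probs)
  if (!any(y) || all(y)) abort("Both classes must be present.")
  mean(probs[y]) - mean(probs[!y])
}

#' Expected/observed ratio with Poisson confidence interval
#'
#' `E/O = sum(predicted probabilities) / observed case count`. Values
#' below 1 indicate risk underestimation, above 1 overestimation. The
#' default 95% interval treats the observed count as Poisson and uses
#' the log-normal approximation `ratio * exp(-+ z / sqrt(O))`; exact
#' Poisson limits (Garwood, via the chi-square quantile identity) are
#' available with `exact = TRUE`.
#'
#' @inheritParams brier_score
#' @param conf_level Confidence level (default 0.95).
#' @param exact Use exact Poisson limits for the observed count.
#' @return Object of class `t2d_eo`: list with `expected`, `observed`,
#'   `ratio`, `ci_low`, `ci_high`, `method`.
#' @export
eo_ratio <- function(probs, labels, conf_level = 0.95, exact = FALSE) {
  y <- as_case(labels)
  check_probs(probs)
  expected <- sum(probs)
  observed <- sum(y)
  if (observed < 1) abort("E/O ratio undefined: zero observed cases.")
  ratio <- expected / observed
  alpha <- 1 - conf_level
  if (exact) {
    o_low <- qchisq(alpha / 2, 2 * observed) / 2
    o_high <- qchisq(1 - alpha / 2, 2 * (observed + 1)) / 2
    ci <- c(expected / o_high, expected / o_low)
  } else {
    z <- qnorm(1 - alpha / 2)
    ci <- ratio * exp(c(-1, 1) * z / sqrt(observed))
  }
  structure(
    list(expected = expected, observed = observed, ratio = ratio,
         ci_low = ci[1], ci_high = ci[2],
         method = if (exact) "poisson_exact" else "poisson_lognormal"),
    class = "t2d_eo"
  )
}

#' @export
print.t2d_eo <- function(x, ...) {
  direction <- if (x$ratio > 1) "overestimates" else if (x$ratio < 1) {
    "underestimates"
  } else "matches"
  cat(sprintf("E/O %.2f [%.2f-%.2f] (E = %.1f, O = %d); model %s observed risk\n",
              x$ratio, x$ci_low, x$ci_high, x$expected, x$observed, direction))
  invisible(x)
}

# quantile bin assignment with tied boundaries merged
quantile_bins <- function(probs, g) {
  br <- unique(quantile(probs, seq(0, 1, length.out = g + 1), names = FALSE))
  if (length(br) < 2) br <- c(br - 1e-9, br + 1e-9)
  cut(probs, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups observations into (by default) deciles of predicted risk
#' (quantile bins, merged when boundaries tie) and compares observed and
#' expected case counts per bin:
#' `chi2 = sum (O_b - E_b)^2 / (E_b (1 - mean p_b))`. For external
#' validation data, where no parameters were estimated from the sample,
#' the statistic is referred to a chi-square with `g` degrees of freedom
#' (`data_role = "validation"`, the default); for data the model was
#' fitted on, the conventional `g - 2` is used
#' (`data_role = "development"`).
#'
#' @inheritParams brier_score
#' @param g Number of risk groups (default 10).
#' @param data_role `"validation"` (df = number of bins) or
#'   `"development"` (df = bins - 2).
#' @return List with `chi2`, `df`, `p_value`, `g_used` (bins after
#'   merging) and the per-bin table.
#' @export
hosmer_lemeshow <- function(probs, labels, g = 10,
                            data_role = c("validation", "development")) {
  data_role <- match.arg(data_role)
  y <- as_case(labels)
  check_probs(probs)
  if (!any(y) || all(y)) abort("Both classes must be present.")
  bin <- quantile_bins(probs, g)
  tab <- tibble(bin = bin, p = probs, y = y) %>%
    group_by(.data$bin) %>%
    summarise(n = n(), observed = sum(.data$y), mean_p = mean(.data$p),
              expected = sum(.data$p), .groups = "drop")
  if (nrow(tab) < 3) abort("Fewer than 3 usable risk groups after merging ties.")
  denom <- tab$expected * (1 - tab$mean_p)
  contrib <- numeric(nrow(tab))
  zero <- denom == 0
  if (any(zero & tab$observed != tab$expected)) {
    abort("Degenerate bin with zero variance but observed != expected.")
  }
  contrib[!zero] <- (tab$observed[!zero] - tab$expected[!zero])^2 / denom[!zero]
  chi2 <- sum(contrib)
  df <- if (data_role == "validation") nrow(tab) else nrow(tab) - 2
  list(chi2 = chi2, df = df,
       p_value = pchisq(chi2, df, lower.tail = FALSE),
       g_used = nrow(tab), bins = tab, data_role = data_role)
}

#' Calibration bins for calibration plots
#'
#' Quantile bins of predicted risk with per-bin mean predicted
#' probability and observed outcome rate — the table behind a
#' calibration curve.
#'
#' @inheritParams hosmer_lemeshow
#' @return Tibble of class `t2d_calbins`: `bin_index`, `n`,
#'   `mean_predicted`, `observed_rate`, `cases`, ordered by
#'   `mean_predicted`.
#' @export
calibration_bins <- function(probs, labels, g = 10) {
  y <- as_case(labels)
  check_probs(probs)
  bin <- quantile_bins(probs, g)
  out <- tibble(bin = bin, p = probs, y = y) %>%
    group_by(.data$bin) %>%
    summarise(n = n(), mean_predicted = mean(.data$p),
              observed_rate = mean(.data$y), cases = sum(.data$y),
              .groups = "drop") %>%
    arrange(.data$mean_predicted) %>%
    mutate(bin_index = row_number()) %>%
    dplyr::select("bin_index", "n", "mean_predicted", "observed_rate", "cases")
  structure(out, class = c("t2d_calbins", class(out)))
}

#' Intercept-update recalibration factor
#'
#' The correction factor is the natural logarithm of the odds ratio of
#' the observed prevalence to the mean predicted risk:
#' `delta = log[ (prev / (1 - prev)) / (pbar / (1 - pbar)) ]`. Adding it
#' to every linear predictor shifts the model's intercept so mean
#' predicted risk moves toward the observed prevalence.
#'
#' @inheritParams brier_score
#' @return The correction factor (log-odds units).
#' @examples
#' recalibration_factor(rep(0.2, 4), c(1, 1, 0, 0)) # log(4)
#' @export
recalibration_factor <- function(probs, labels) {
  y <- as_case(labels)
  check_probs(probs, open = TRUE)
  prev <- mean(y)
  pbar <- mean(probs)
  if (prev <= 0 || prev >= 1) {
    abort("Observed prevalence must be strictly inside (0, 1).")
  }
  log((prev / (1 - prev)) / (pbar / (1 - pbar)))
}

#' Apply intercept-update recalibration
#'
#' Shifts every predicted probability on the log-odds scale:
#' `p' = plogis(qlogis(p) + delta)`. `mode = "one_step"` applies the
#' supplied (or computed) factor once — for heterogeneous probabilities
#' this moves, but does not make, E/O exactly 1. `mode = "iterated"`
#' repeats compute-factor-then-apply until `|sum(p') - sum(y)| <
#' tol * sum(y)` — i.e. until `|E/O - 1| < tol` — for at most
#' `max_iter` iterations, driving E/O to 1. The
#' shift is strictly monotone, so the ranking of probabilities — and
#' hence the C-statistic — is preserved exactly.
#'
#' @param probs Predicted probabilities strictly inside (0, 1).
#' @param correction_factor Log-odds shift; if `NULL`, computed from
#'   `labels` via [recalibration_factor()].
#' @param labels Case indicators (required when `correction_factor` is
#'   `NULL` or `mode = "iterated"`).
#' @param mode `"one_step"` (default) or `"iterated"`.
#' @param tol Relative convergence tolerance on E/O for iterated mode.
#' @param max_iter Iteration cap for iterated mode.
#' @return Object of class `t2d_recal`: list with `correction_factor`
#'   (total applied shift), `mode`, `probabilities_before`,
#'   `probabilities_after`, `n_iter`, `converged`.
#' @export
apply_recalibration <- function(probs, correction_factor = NULL, labels = NULL,
                                mode = c("one_step", "iterated"),
                                tol = 1e-6, max_iter = 100) {
  mode <- match.arg(mode)
  check_probs(probs, open = TRUE)
  if (is.null(correction_factor) || mode == "iterated") {
    if (is.null(labels)) {
      abort("`labels` required to compute the correction factor.")
    }
  }
  before <- probs
  if (mode == "one_step") {
    delta <- correction_factor %||% recalibration_factor(probs, labels)
    after <- if (delta == 0) probs else plogis(qlogis(probs) + delta)
    return(structure(
      list(correction_factor = delta, mode = mode,
           probabilities_before = before, probabilities_after = after,
           n_iter = 1L, converged = TRUE),
      class = "t2d_recal"
    ))
  }
  y <- as_case(labels)
  total <- correction_factor %||% 0
  after <- if (total != 0) plogis(qlogis(probs) + total) else probs
  n <- length(probs)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- recalibration_factor(after, y)
    total <- total + step
    after <- plogis(qlogis(after) + step)
    if (abs(sum(after) - sum(y)) < tol * sum(y)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(sprintf("Iterated recalibration did not converge in %d iterations.",
                  max_iter))
  }
  structure(
    list(correction_factor = total, mode = mode,
         probabilities_before = before, probabilities_after = after,
         n_iter = iter, converged = converged),
    class = "t2d_recal"
  )
}

#' @export
print.t2d_recal <- function(x, ...) {
  cat(sprintf("Intercept-update recalibration (%s): delta = %.6f after %d iteration(s)\n",
              x$mode, x$correction_factor, x$n_iter))
  invisible(x)
}
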