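#' Tidy methods for t2dval result objects
#'
#' Broom-style accessors: `tidy()` returns a tibble of estimates,
#' `glance()` a one-row model-level summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name t2dval-tidiers
NULL

#' @rdname t2dval-tidiers
#' @method tidy t2d_cstat
#' @export
tidy.t2d_cstat <- function(x, ...) {
  tibble(
    estimate = x$c, std.error = x$se,
    conf.low = x$ci_low, conf.high = x$ci_high,
    n_cases = x$n_cases, n_noncases = x$n_noncases,
    interpretation = interpret_c(x$c)
  )
}

#' @rdname t2dval-tidiers
#' @method tidy t2d_eo
#' @export
tidy.t2d_eo <- function(x, ...) {
  tibble(
    expected = x$expected, observed = x$observed,
    estimate = x$ratio, conf.low = x$ci_low, conf.high = x$ci_high,
    direction = dplyr::case_when(
      x$ratio > 1 ~ "overestimation",
      x$ratio < 1 ~ "underestimation",
      TRUE ~ "exact"
    ),
    method = x$method
  )
}

#' @rdname t2dval-tidiers
#' @method tidy t2d_recal
#' @export
tidy.t2d_recal <- function(x, ...) {
  tibble(
    index = seq_along(x$probabilities_before),
    before = x$probabilities_before,
    after = x$probabilities_after
  )
}

#' @rdname t2dval-tidiers
#' @method glance t2d_recal
#' @export
glance.t2d_recal <- function(x, ...) {
  tibble(
    correction_factor = x$correction_factor, mode = x$mode,
    n_iter = x$n_iter, converged = x$converged,
    mean_before = mean(x$probabilities_before),
    mean_after = mean(x$probabilities_after)
  )
}

#' @rdname t2dval-tidiers
#' @method tidy t2d_validation
#' @export
tidy.t2d_validation <- function(x, ...) x$cells

#' @rdname t2dval-tidiers
#' @method glance t2d_validation
#' @export
glance.t2d_validation <- function(x, ...) {
  tibble(
    n_models = length(x$meta$models),
    n_criteria = length(x$meta$criteria),
    n_cells = nrow(x$cells),
    n_subgroup_rows = nrow(x$subgroups),
    n_errors = nrow(x$errors),
    n_warnings = nrow(x$warnings),
    recalibrate = x$meta$recalibrate
  )
}
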