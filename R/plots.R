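#' Plot a ROC curve
#'
#' @param object A `t2d_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot t2d_roc
#' @export
autoplot.t2d_roc <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC curve (area %.3f)", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a calibration curve from binned predictions
#'
#' Mean predicted risk against observed outcome rate per risk decile;
#' the dashed identity line is perfect calibration.
#'
#' @param object A `t2d_calbins` from [calibration_bins()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot t2d_calbins
#' @export
autoplot.t2d_calbins <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$mean_predicted,
                               y = .data$observed_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), colour = "steelblue") +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(x = "Mean predicted risk", y = "Observed rate",
                  title = "Calibration") +
    ggplot2::theme_minimal()
}

#' Forest plot of the validation grid
#'
#' C-statistics (with confidence intervals) and E/O ratios per model,
#' criterion and calibration state.
#'
#' @param object A `t2d_validation` from [run_validation()].
#' @param statistic `"c"` (default) or `"eo"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot t2d_validation
#' @export
autoplot.t2d_validation <- function(object, statistic = c("c", "eo"), ...) {
  statistic <- match.arg(statistic)
  cells <- object$cells
  if (statistic == "c") {
    cells <- dplyr::filter(cells, .data$state == "original")
    ggplot2::ggplot(cells,
                    ggplot2::aes(x = .data$c, y = .data$model,
                                 colour = .data$criterion)) +
      ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed",
                          colour = "grey60") +
      ggplot2::geom_pointrange(
        ggplot2::aes(xmin = .data$c_low, xmax = .data$c_high),
        position = ggplot2::position_dodge(width = 0.4)) +
      ggplot2::labs(x = "C-statistic (95% CI)", y = NULL,
                    title = "Discrimination by model and criterion") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(cells,
                    ggplot2::aes(x = .data$eo, y = .data$model,
                                 colour = .data$criterion,
                                 shape = .data$state)) +
      ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                          colour = "grey60") +
      ggplot2::geom_pointrange(
        ggplot2::aes(xmin = .data$eo_low, xmax = .data$eo_high),
        position = ggplot2::position_dodge(width = 0.5)) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "E/O ratio (95% CI, log scale)", y = NULL,
                    title = "Calibration by model, criterion and state") +
      ggplot2::theme_minimal()
  }
}
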