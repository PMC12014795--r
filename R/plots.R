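#' Plot a study result
#'
#' `type = "agreement"` shows GTV agreement of tumour areas by H-Score group
#' (the pattern expected under the linear uptake model is a rising staircase);
#' `type = "uptake"` shows SUVmean by group; `type = "regression"` shows
#' SUVmean against H-Score for tumour areas with the through-origin fit of
#' the large-area subset.
#'
#' @param object a `study_result` from [run_study()].
#' @param type which panel to draw.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot study_result
#' @export
autoplot.study_result <- function(object,
                                  type = c("agreement", "uptake",
                                           "regression"), ...) {
  type <- match.arg(type)
  ta <- object$units[object$units$unit_kind == "tumour_area", ]
  ta$group <- factor(ta$group, levels = object$config$scheme$group)
  if (type == "agreement") {
    return(
      ggplot2::ggplot(ta, ggplot2::aes(x = .data$group,
                                       y = .data$gtv_agreement)) +
        ggplot2::geom_boxplot() +
        ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
        ggplot2::scale_y_continuous(labels = function(v) 100 * v) +
        ggplot2::labs(x = "H-Score group", y = "GTV agreement (%)")
    )
  }
  if (type == "uptake") {
    return(
      ggplot2::ggplot(ta, ggplot2::aes(x = .data$group, y = .data$suv_mean)) +
        ggplot2::geom_boxplot() +
        ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
        ggplot2::labs(x = "H-Score group", y = "SUVmean (g/ml)")
    )
  }
  reg <- object$regressions
  reg <- reg[reg$subset == "area_gt_threshold" & reg$metric == "suv_mean", ]
  p <- ggplot2::ggplot(ta, ggplot2::aes(x = .data$hscore_mean,
                                        y = .data$suv_mean,
                                        colour = .data$cohort)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "H-Score", y = "SUVmean (g/ml)")
  if (nrow(reg) == 1L) {
    p <- p + ggplot2::geom_abline(intercept = 0, slope = reg$slope,
                                  colour = "red")
  }
  p
}

#' Plot a through-origin regression fit
#'
#' Scatter of the fitted data with the through-origin regression line.
#'
#' @param object an `origin_fit` from [regress_through_origin()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot origin_fit
#' @export
autoplot.origin_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = 0, slope = object$slope, colour = "red") +
    ggplot2::labs(
      x = "H-Score", y = "SUV (g/ml)",
      subtitle = sprintf("slope %.3g +/- %.2g, uncentered R^2 = %.2f",
                         object$slope, object$slope_se, object$r_squared))
}
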