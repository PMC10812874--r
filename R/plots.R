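#' @include AllClasses.R curves.R
NULL

utils::globalVariables(c("size", "condition", "stderr"))

#' Plot learning curves on log-log axes
#'
#' Mean test MSE versus training-set size for each condition, with
#' standard-error ribbons, both axes log-scaled so the power-law region
#' appears as a straight line.
#'
#' @param curves a [LearningCurve-class] or a list of them.
#' @return a ggplot object.
#' @export
plotLearningCurves <- function(curves) {
  if (methods::is(curves, "LearningCurve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, function(cv) curveTables(cv)$summary))
  df$condition <- paste(df$modality, df$learner, sep = " / ")
  ggplot2::ggplot(df, ggplot2::aes(x = size, y = mean, colour = condition,
                                   fill = condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - stderr,
                                      ymax = mean + stderr),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "training set size (pairs)", y = "test MSE",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_bw()
}
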