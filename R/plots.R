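# ggplot2 views of the three headline analyses: ROC, calibration, decision
# curve, plus the strata bar.

roc_points <- function(predictions, outcomes) {
  outcomes <- check_two_classes(outcomes)
  ord <- order(predictions, decreasing = TRUE)
  y <- outcomes[ord]
  p <- predictions[ord]
  keep <- c(!duplicated(p)[-1], TRUE)  # step after each distinct value
  tibble::tibble(
    fpr = c(0, cumsum(y == 0)[keep] / sum(y == 0)),
    tpr = c(0, cumsum(y == 1)[keep] / sum(y == 1))
  )
}

#' ROC curve plot
#'
#' @param predictions Predicted probabilities or scores.
#' @param outcomes Binary outcomes.
#' @return A ggplot: the empirical ROC curve with the chance diagonal and
#'   the Mann-Whitney AUC in the subtitle.
#' @export
plot_roc <- function(predictions, outcomes) {
  pts <- roc_points(predictions, outcomes)
  auc <- auc_mann_whitney(predictions, outcomes)
  ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = "ROC curve",
                  subtitle = sprintf("AUC = %.3f", auc)) +
    ggplot2::theme_minimal()
}

#' Calibration plot
#'
#' Decile points of observed versus predicted risk with the LOESS-smoothed
#' calibration curve, against the ideal 45-degree line.
#'
#' @inheritParams plot_roc
#' @param n_bins Number of equal-count bins for the points.
#' @param span LOESS neighborhood fraction.
#' @return A ggplot.
#' @export
plot_calibration <- function(predictions, outcomes, n_bins = 10, span = 0.75) {
  bins <- dplyr::filter(calibration_bins(predictions, outcomes, n_bins),
                        !.data$empty)
  curve <- loess_curve(predictions, outcomes, span)
  ggplot2::ggplot() +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(.data$pred, .data$smoothed),
                       linewidth = 0.8) +
    ggplot2::geom_point(data = bins,
                        ggplot2::aes(.data$pred_mean, .data$obs_rate),
                        size = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Predicted probability of success",
                  y = "Observed proportion",
                  title = "Calibration") +
    ggplot2::theme_minimal()
}

#' Decision-curve plot
#'
#' @param x An `ecv_decision_curve` tibble from [net_benefit()].
#' @param ... Unused.
#' @return A ggplot of model, treat-all and treat-none net benefit.
#' @export
plot_decision_curve <- function(x, ...) {
  stopifnot(inherits(x, "ecv_decision_curve"))
  long <- tidyr::pivot_longer(tibble::as_tibble(x),
                              cols = c("nb_model", "nb_treat_all", "nb_treat_none"),
                              names_to = "strategy", values_to = "net_benefit")
  long$strategy <- dplyr::recode(long$strategy, nb_model = "PRE-ECV model",
                                 nb_treat_all = "Treat all",
                                 nb_treat_none = "Treat none")
  ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$net_benefit,
                                     colour = .data$strategy,
                                     linetype = .data$strategy)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(-0.05, NA)) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                  colour = NULL, linetype = NULL,
                  title = "Decision curve analysis") +
    ggplot2::theme_minimal()
}

#' @rdname plot_decision_curve
#' @param object An `ecv_decision_curve`.
#' @export
autoplot.ecv_decision_curve <- function(object, ...) {
  plot_decision_curve(object, ...)
}

#' Strata success-rate plot
#'
#' @param strata A tibble from [strata_rates()].
#' @return A ggplot of per-stratum observed success rates with Wilson
#'   interval bars.
#' @export
plot_strata <- function(strata) {
  strata$stratum <- factor(strata$stratum, levels = strata$stratum)
  ggplot2::ggplot(strata, ggplot2::aes(.data$stratum, .data$rate)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low,
                                        ymax = .data$conf.high),
                           width = 0.2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Score stratum", y = "Observed success rate",
                  title = "Success by score stratum") +
    ggplot2::theme_minimal()
}
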