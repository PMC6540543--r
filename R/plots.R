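#' Plot Kaplan-Meier curves for a median-dichotomized survival analysis
#'
#' Step curves per expression group, annotated with the log-rank p-value.
#'
#' @param survival_result A [survival_by_median()] result.
#' @return A ggplot object.
#' @export
plot_km <- function(survival_result) {
  km <- survival_result$km
  start <- km |>
    group_by(.data$group) |>
    summarise(time = 0, surv = 1, .groups = "drop")
  dat <- bind_rows(start, select(km, "group", "time", "surv"))
  ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$surv, colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = "Expression",
                  subtitle = sprintf("log-rank p = %.3g",
                                     survival_result$logrank$p)) +
    ggplot2::theme_minimal()
}

#' @describeIn roc_auc Plot the ROC curve with its AUC.
#' @param object A `roc_result`.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("AUC = %.3f (positive: %s)",
                                     object$auc, object$positive_label)) +
    ggplot2::theme_minimal()
}

#' Plot detection-competency curves
#'
#' DEG counts per combination method across the FDR threshold grid, the
#' standard display for comparing how many genes each method detects.
#'
#' @param competency A [detection_competency()] table.
#' @return A ggplot object.
#' @export
plot_detection_competency <- function(competency) {
  ggplot2::ggplot(competency,
                  ggplot2::aes(.data$threshold, .data$n_deg,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "FDR threshold", y = "DEGs detected", colour = "Method") +
    ggplot2::theme_minimal()
}
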