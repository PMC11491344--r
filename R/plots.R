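# ggplot2 visualisations

#' Plot a ROC curve
#' @param object A `sir_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sir_roc <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.7, colour = "#2166AC") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC, AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Dot-and-interval plot of mediation effects
#' @param object A `sir_mediation` from [run_mediation()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sir_mediation <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$effect != "prop_mediated")
  df$effect <- factor(df$effect, levels = c("total", "ade", "acme"),
                      labels = c("Total effect", "Direct (ADE)",
                                 "Mediated (ACME)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$effect)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.15, colour = "#2166AC") +
    ggplot2::geom_point(size = 2.2, colour = "#2166AC") +
    ggplot2::labs(x = "Effect on P(late onset window)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of SIR against onset-to-MRI time by LVO status
#'
#' The diagnostic scatter behind the lesion-age interpretation of SIR:
#' FLAIR relative hyperintensity grows with time from onset, with
#' separate loess trends for patients with and without large vessel
#' occlusion.
#'
#' @param cohort A cohort tibble with `onset_to_mri_h`, `sir`, `lvo`.
#' @return A ggplot.
#' @export
plot_sir_time <- function(cohort) {
  ggplot2::ggplot(cohort,
                  ggplot2::aes(x = .data$onset_to_mri_h, y = .data$sir,
                               colour = .data$lvo)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.9) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "#2166AC",
                                            `TRUE` = "#B2182B"),
                                 labels = c("no LVO", "LVO"),
                                 name = NULL) +
    ggplot2::labs(x = "Onset-to-MRI time (h)",
                  y = "FLAIR signal-intensity ratio") +
    ggplot2::theme_minimal()
}
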