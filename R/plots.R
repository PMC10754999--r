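#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot class mean spectra with envelopes
#'
#' Mean absorbance per class (lines) with the pointwise min--max envelope
#' (shading). Following spectroscopy convention the wavenumber axis runs
#' descending left to right; set `reverse_x = FALSE` for an ascending axis.
#'
#' @param object A [spectra_tbl()].
#' @param reverse_x Draw the wavenumber axis descending (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectra_tbl <- function(object, reverse_x = TRUE, ...) {
  stats <- mean_spectrum_by_class(object)
  p <- ggplot2::ggplot(stats, ggplot2::aes(x = .data$wavenumber)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                                      fill = .data$class_label), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean, colour = .data$class_label)) +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)), y = "Absorbance (a.u.)",
                  colour = "Class", fill = "Class")
  if (reverse_x) p <- p + ggplot2::scale_x_reverse()
  p
}

#' Plot one-vs-rest ROC curves
#'
#' One curve per class with the AUC in the legend and the chance diagonal.
#'
#' @param object A `roc_result` from [roc_auc_ovr()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  lab <- stats::setNames(
    sprintf("%s (AUC %.3f)", object$auc$class, object$auc$auc),
    object$auc$class
  )
  curves <- dplyr::mutate(object$curves,
                          class = factor(lab[.data$class], levels = unname(lab)))
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL,
                  subtitle = sprintf("macro AUC %.3f", object$macro_auc))
}

#' Plot headline metrics as bars
#'
#' Accuracy, sensitivity, precision and specificity as a four-bar chart.
#'
#' @param object A `metrics_report` from [macro_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metrics_report <- function(object, ...) {
  d <- tidyr::pivot_longer(glance(object), dplyr::everything(),
                           names_to = "metric", values_to = "value")
  d$metric <- factor(d$metric,
                     levels = c("accuracy", "sensitivity", "precision", "specificity"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.4f", .data$value)),
                       vjust = -0.4, size = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1.05)) +
    ggplot2::labs(x = NULL, y = "Value")
}

#' Plot a model comparison
#'
#' Headline metrics per model, grouped bars.
#'
#' @param object A `spectranet_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectranet_experiment <- function(object, ...) {
  tb <- benchmark_table(object)
  d <- tidyr::pivot_longer(
    tb[, c("model", "accuracy", "sensitivity", "precision", "specificity")],
    -"model", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value,
                                  fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Value", fill = "Model")
}
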