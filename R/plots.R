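#' Plot selection frequencies
#'
#' Horizontal bar chart of per-feature selection frequencies across the
#' leave-one-out folds, signature members highlighted and the threshold
#' `tau` drawn as a vertical line (the layout of the original signature
#' figure).
#'
#' @param object A `selection_report`.
#' @param min_frequency Hide features below this display threshold
#'   (reporting-only; it is not a selection rule).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selection_report <- function(object, min_frequency = 0.03, ...) {
  df <- tidy(object) %>% filter(.data$frequency >= min_frequency)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$frequency,
    y = stats::reorder(.data$feature, .data$frequency),
    fill = .data$in_signature
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$tau, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey65"),
                               name = "In signature") +
    ggplot2::labs(x = "Selection frequency across LOO folds", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the pooled ROC curve
#'
#' ROC curve of the pooled leave-one-out predictions with the AUC in the
#' subtitle.
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  subtitle = sprintf("Pooled LOO ROC, AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.selection_report
#' @export
autoplot.signature_run <- function(object, ...) {
  autoplot(object$evaluation)
}
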