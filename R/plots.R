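#' Plot a target-decoy ROC curve
#'
#' @param object A `fuco_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fuco_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Decoy rate (FPR)", y = "Target rate (TPR)",
      title = sprintf("Target-decoy ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param object A `fuco_eval` from [evaluate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fuco_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$manual,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(FUCO_CLASSES)) +
    ggplot2::scale_x_discrete(limits = FUCO_CLASSES) +
    ggplot2::labs(x = "Predicted class", y = "Manual class",
                  title = sprintf("Accuracy %.2f%%", 100 * object$accuracy)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Mean diagnostic-ion profile by class
#'
#' Summarises a labelled feature table as the mean relative intensity of
#' each of the 14 diagnostic ions per fucosylation class — the
#' feature-space picture of the pairing rule (fucosylated Y ions light up
#' for core, fucosylated B ions for outer, both for dual).
#'
#' @param features A labelled feature tibble from [extract_features()].
#' @return A ggplot object.
#' @export
plot_feature_profile <- function(features) {
  long <- tidyr::pivot_longer(
    dplyr::select(features, "label", dplyr::all_of(ION_LABELS)),
    cols = dplyr::all_of(ION_LABELS),
    names_to = "ion", values_to = "rel_intensity"
  )
  long$ion <- factor(long$ion, levels = ION_LABELS)
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$label, .data$ion),
    mean_intensity = mean(.data$rel_intensity), .groups = "drop"
  )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$ion, y = .data$mean_intensity)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$label), ncol = 1) +
    ggplot2::labs(x = "Diagnostic ion", y = "Mean relative intensity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Pscore distributions of targets and decoys
#'
#' @param target_scores,decoy_scores Numeric Pscore vectors.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_pscore_distributions <- function(target_scores, decoy_scores, bins = 40) {
  df <- dplyr::bind_rows(
    tibble(pscore = target_scores, set = "target"),
    tibble(pscore = decoy_scores, set = "decoy")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pscore, fill = .data$set)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6, position = "identity") +
    ggplot2::labs(x = "Pscore", y = "GSMs", fill = NULL) +
    ggplot2::theme_minimal()
}
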