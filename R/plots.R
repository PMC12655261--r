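#' ROC curve of a LOOCV run
#'
#' @param object A [loocv()] result.
#' @param ... Unused.
#' @return A ggplot: ROC curve of the ensemble score with the AUC in
#'   the subtitle and the chance diagonal for reference.
#' @export
autoplot.drugspace_loocv <- function(object, ...) {
  p <- object$predictions
  thresholds <- c(Inf, sort(unique(p$ensemble_score), decreasing = TRUE))
  roc <- purrr::map_dfr(thresholds, function(t) {
    pred <- as.integer(p$ensemble_score >= t)
    tibble(
      tpr = sum(pred == 1L & p$truth == 1L) / sum(p$truth == 1L),
      fpr = sum(pred == 1L & p$truth == 0L) / sum(p$truth == 0L)
    )
  })
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = "Majority-voting ensemble ROC (LOOCV)",
      subtitle = sprintf("AUC = %.4f", object$metrics$auc),
      x = "False positive rate", y = "True positive rate"
    ) +
    ggplot2::theme_minimal()
}

#' Null accuracy distribution of a permutation test
#'
#' @param object A [permutation_test()] result.
#' @param ... Unused.
#' @return A ggplot: histogram of permuted-label accuracies with the
#'   observed accuracy marked.
#' @export
autoplot.drugspace_permutation <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$null_accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed_accuracy,
                        colour = "#d7301f", linewidth = 0.8) +
    ggplot2::labs(
      title = "Permutation null distribution of LOOCV accuracy",
      subtitle = sprintf("observed %.2f%%, p = %.4g",
                         object$observed_accuracy, object$p_value),
      x = "Accuracy under shuffled labels (%)", y = "Permutations"
    ) +
    ggplot2::theme_minimal()
}

#' Intra- versus inter-class pairwise distance distributions
#'
#' Violin plots per metric comparing distances between same-class chain
#' pairs against different-class pairs; well-separated features show
#' inter-class distances clearly above intra-class ones.
#'
#' @param matrices Named list of `distance_matrix` objects.
#' @param labels Tibble `chain_id, label` or named 0/1 vector.
#' @return A ggplot, faceted by metric (free y scales, since the
#'   metrics live on different scales).
#' @export
plot_distance_distributions <- function(matrices, labels) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.integer(labels$label), labels$chain_id)
  }
  long <- purrr::map_dfr(names(matrices), function(mn) {
    d <- tidy(matrices[[mn]])
    d$metric <- mn
    d$pair <- ifelse(labels[d$chain_a] == labels[d$chain_b],
                     "intra-class", "inter-class")
    d
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pair, y = .data$distance,
                                     fill = .data$pair)) +
    ggplot2::geom_violin(draw_quantiles = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c("intra-class" = "#74a9cf",
                                          "inter-class" = "#fec44f")) +
    ggplot2::labs(x = NULL, y = "Pairwise distance") +
    ggplot2::theme_minimal()
}

#' Neighbour-quality diagnostic panels
#'
#' @param diagnostics A [neighbor_diagnostics()] table.
#' @return A ggplot: distance-based confidence by prediction
#'   correctness, faceted by metric.
#' @export
plot_neighbor_diagnostics <- function(diagnostics) {
  ggplot2::ggplot(
    diagnostics,
    ggplot2::aes(x = .data$correct, y = .data$confidence, fill = .data$correct)
  ) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_fill_manual(values = c("TRUE" = "#41ab5d",
                                          "FALSE" = "#fe9929")) +
    ggplot2::labs(x = "Prediction correct", y = "Distance-based confidence") +
    ggplot2::theme_minimal()
}
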