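# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_col
#'   geom_tile geom_text labs theme_minimal coord_equal scale_fill_gradient
NULL

#' Plot a ROC curve
#'
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line(colour = "#2c7fb8", linewidth = 0.8) +
    coord_equal() +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC (AUC = %.4f)", object$auc)) +
    theme_minimal()
}

#' Plot a jackknife confusion matrix
#'
#' @param object A `jackknife_report`.
#' @param ... Unused.
#' @return A ggplot heat map of the confusion counts.
#' @export
autoplot.jackknife_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "n")
  ggplot(df, aes(x = .data$predicted, y = .data$truth, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n), colour = "grey20") +
    scale_fill_gradient(low = "white", high = "#2c7fb8") +
    labs(title = sprintf("Jackknife confusion (overall accuracy %.3f)",
                         object$overall_accuracy),
         x = "Predicted class", y = "True class") +
    theme_minimal()
}

#' Plot the block composition of the top-ranked features
#'
#' Bar chart of how many of the `k` best-ranked features come from each
#' feature block (the usual view of where the discriminative signal lives).
#'
#' @param ranking A `svm_rfe_ranking`.
#' @param k Number of top features to summarize (default 322).
#' @return A ggplot.
#' @export
plot_block_composition <- function(ranking, k = 322) {
  stopifnot(inherits(ranking, "svm_rfe_ranking"))
  k <- min(k, length(ranking$rank_list))
  tab <- table(factor(feature_block(utils::head(ranking$rank_list, k)),
                      levels = c("pssm_lpc", "profeat", "go")))
  df <- data.frame(block = names(tab), n = as.integer(tab))
  ggplot(df, aes(x = .data$block, y = .data$n)) +
    geom_col(fill = "#2c7fb8") +
    labs(x = "Feature block", y = sprintf("Features in top %d", k)) +
    theme_minimal()
}
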