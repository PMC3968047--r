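# Jackknife (leave-one-out) evaluation: confusion matrix, per-class accuracy,
# per-class Matthews correlation coefficient, overall accuracy, and
# macro-averaged one-vs-rest ROC curves from decision values.

#' Matthews correlation coefficient from binary counts
#'
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); returns 0 when
#' any denominator factor is 0 (the usual convention for degenerate margins).
#' Vectorized over its arguments.
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return Numeric in \[-1, 1\].
#' @export
#' @examples
#' mcc_from_counts(10, 0, 10, 0)  # 1
mcc_from_counts <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  num <- tp * tn - fp * fn
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  ifelse(den == 0, 0, num / den)
}

#' Confusion matrix with fixed class order
#'
#' @param truth,predicted Factors/labels over the structural classes (or any
#'   shared label set if `levels` is given).
#' @param levels Class order; defaults to [structural_classes()] restricted
#'   to the observed labels, or the union of observed labels otherwise.
#' @return k x k integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  if (is.null(levels)) {
    obs <- unique(c(as.character(truth), as.character(predicted)))
    levels <- if (all(obs %in% structural_classes())) {
      intersect(structural_classes(), obs)
    } else {
      sort(obs)
    }
  }
  t1 <- factor(as.character(truth), levels = levels)
  t2 <- factor(as.character(predicted), levels = levels)
  unclass(table(truth = t1, predicted = t2))
}

# per-class binarized counts from a confusion matrix
class_counts <- function(cm) {
  n <- sum(cm)
  purrr::map_dfr(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tibble::tibble(class = rownames(cm)[[i]], tp = tp, fp = fp,
                   tn = n - tp - fn - fp, fn = fn)
  })
}

#' Build an evaluation report from truth and predictions
#'
#' @param truth,predicted Label vectors.
#' @param decision_values Optional n x k matrix of one-vs-rest decision
#'   values (for downstream ROC curves).
#' @param levels Optional class order.
#' @return Object of class `jackknife_report`: confusion matrix, per-class
#'   accuracy and MCC, overall accuracy, and the per-sample predictions.
#' @export
evaluation_report <- function(truth, predicted, decision_values = NULL,
                              levels = NULL) {
  cm <- confusion_matrix(truth, predicted, levels)
  counts <- class_counts(cm)
  per_class <- dplyr::mutate(
    counts,
    n = .data$tp + .data$fn,
    accuracy = ifelse(.data$n > 0, .data$tp / .data$n, NA_real_),
    mcc = mcc_from_counts(.data$tp, .data$fp, .data$tn, .data$fn)
  )
  structure(list(
    confusion = cm,
    per_class = per_class[, c("class", "n", "accuracy", "mcc")],
    overall_accuracy = sum(diag(cm)) / sum(cm),
    n = sum(cm),
    predictions = tibble::tibble(truth = as.character(truth),
                                 predicted = as.character(predicted)),
    decision_values = decision_values
  ), class = "jackknife_report")
}

#' @export
print.jackknife_report <- function(x, ...) {
  cat("<jackknife_report> n = ", x$n, ", overall accuracy = ",
      sprintf("%.4f", x$overall_accuracy), "\n", sep = "")
  print(x$per_class)
  invisible(x)
}

#' @export
#' @method tidy jackknife_report
#' @rdname evaluation_report
#' @param x,... For `tidy()`/`glance()`: a report and ignored dots.
tidy.jackknife_report <- function(x, ...) x$per_class

#' @export
#' @importFrom generics glance
#' @method glance jackknife_report
#' @rdname evaluation_report
glance.jackknife_report <- function(x, ...) {
  tibble::tibble(n = x$n, overall_accuracy = x$overall_accuracy,
                 mean_mcc = mean(x$per_class$mcc))
}

#' Jackknife (leave-one-out) evaluation of the SVM pipeline
#'
#' For each sample i, trains on the other N - 1 samples and predicts sample
#' i; aggregates the N held-out predictions into a confusion matrix with
#' per-class accuracy and MCC, and stores each sample's one-vs-rest decision
#' values for ROC analysis.
#'
#' Two selection protocols are available. `"rank_once"` ranks (or takes
#' a precomputed ranking) on the full dataset, truncates once to the top-k
#' features, and only the classifier is jackknifed; this mirrors the
#' rank-then-validate protocol and carries its optimistic selection bias.
#' `"nested"` re-runs SVM-RFE inside every fold on the N - 1 training samples
#' before truncation, which is unbiased but far more expensive.
#'
#' @param data Feature tibble.
#' @param params An [svm_params()].
#' @param protocol `"rank_once"` or `"nested"`.
#' @param ranking Optional precomputed `svm_rfe_ranking`
#'   (protocol `"rank_once"` only).
#' @param k Optional top-k truncation applied with the protocol above; NULL
#'   uses all features.
#' @param rfe_cost Linear-SVM C for any ranking computed internally.
#' @return A `jackknife_report` (see [evaluation_report()]); its
#'   `decision_values` matrix has one row per sample and one column per class.
#' @export
jackknife <- function(data, params = svm_params(),
                      protocol = c("rank_once", "nested"),
                      ranking = NULL, k = NULL, rfe_cost = 1) {
  protocol <- match.arg(protocol)
  parts <- feature_matrix_parts(data)
  y <- droplevels(parts$y)
  n <- nrow(data)
  if (n < nlevels(y) + 1) stop("too few samples for jackknife", call. = FALSE)
  if (any(table(y) < 2)) {
    stop("jackknife fold would lose an entire class: every class needs >= 2 samples",
         call. = FALSE)
  }
  if (protocol == "rank_once" && !is.null(k)) {
    if (is.null(ranking)) ranking <- svm_rfe(data, cost = rfe_cost)
    data <- top_k(data, ranking, k)
  }
  classes <- levels(y)
  preds <- character(n)
  dvals <- matrix(NA_real_, n, length(classes),
                  dimnames = list(data$protein_id, classes))
  for (i in seq_len(n)) {
    tr <- data[-i, , drop = FALSE]
    if (protocol == "nested" && !is.null(k)) {
      fold_rank <- svm_rfe(tr, cost = rfe_cost)
      tr <- top_k(tr, fold_rank, k)
      te <- data[i, c(id_columns(), fold_rank$rank_list[seq_len(k)]), drop = FALSE]
    } else {
      te <- data[i, , drop = FALSE]
    }
    model <- svm_train(tr, params)
    out <- predict(model, te, decision_values = TRUE)
    preds[[i]] <- as.character(out$class)
    dvals[i, colnames(out$ovr)] <- out$ovr[1, ]
  }
  evaluation_report(as.character(data$class), preds, decision_values = dvals,
                    levels = classes)
}

#' Write a report as JSON plus a predictions TSV
#'
#' @param report A `jackknife_report`.
#' @param json_path Output JSON path (confusion + metrics).
#' @param tsv_path Optional per-sample predictions TSV path.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, tsv_path = NULL) {
  obj <- list(
    n = report$n,
    overall_accuracy = report$overall_accuracy,
    per_class = report$per_class,
    confusion = list(classes = rownames(report$confusion),
                     counts = unclass(report$confusion))
  )
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path)) {
    utils::write.table(report$predictions, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(json_path)
}
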