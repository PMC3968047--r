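# One-vs-rest ROC curves from decision values, vertical (TPR) averaging on a
# common FPR grid, and trapezoidal AUC.

#' One-vs-rest ROC curve
#'
#' Sweeps a threshold over the unique decision values (plus sentinels) so the
#' curve runs from (0, 0) to (1, 1); AUC is the trapezoidal integral.
#'
#' @param scores Numeric decision values (higher = more positive).
#' @param labels Class labels.
#' @param positive The positive class; all other labels are the rest.
#' @return Object of class `roc_curve`: tibble `points` (`fpr`, `tpr`,
#'   non-decreasing fpr) and scalar `auc`.
#' @export
roc_one_vs_rest <- function(scores, labels, positive) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  pos <- as.character(labels) == as.character(positive)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs at least one positive and one negative sample", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # cumulative counts at each distinct threshold
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[keep]
  fp <- cumsum(!p)[keep]
  pts <- tibble::tibble(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  structure(list(points = pts, auc = auc, positive = as.character(positive)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", if (!is.null(x$positive)) paste0(x$positive, ", "),
      nrow(x$points), " points, AUC = ", sprintf("%.4f", x$auc), "\n", sep = "")
  invisible(x)
}

# TPR of a curve at given FPR values (linear interpolation between vertices)
interp_tpr <- function(curve, fpr_grid) {
  stats::approx(curve$points$fpr, curve$points$tpr, xout = fpr_grid,
                method = "linear", ties = max, rule = 2)$y
}

#' Macro-average ROC curves
#'
#' Vertical (TPR) averaging of several one-vs-rest curves on a common FPR
#' grid of `grid_size` points; AUC is recomputed by trapezoid on the grid.
#'
#' @param curves List of `roc_curve` objects.
#' @param grid_size Number of FPR grid points (default 101).
#' @return A `roc_curve` on the common grid.
#' @export
average_roc <- function(curves, grid_size = 101) {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, logical(1), "roc_curve")))
  grid <- seq(0, 1, length.out = grid_size)
  tprs <- vapply(curves, interp_tpr, numeric(grid_size), fpr_grid = grid)
  avg <- rowMeans(tprs)
  pts <- tibble::tibble(fpr = grid, tpr = avg)
  auc <- sum(diff(grid) * (avg[-1] + avg[-grid_size]) / 2)
  structure(list(points = pts, auc = auc, positive = NULL),
            class = "roc_curve")
}

#' Macro-averaged one-vs-rest ROC from a jackknife report
#'
#' Builds the four one-vs-rest curves from the report's stored decision
#' values and averages them.
#'
#' @param report A `jackknife_report` carrying decision values.
#' @param grid_size Grid for [average_roc()].
#' @return List with `per_class` (named list of `roc_curve`) and `macro`
#'   (the averaged `roc_curve`).
#' @export
report_roc <- function(report, grid_size = 101) {
  dv <- report$decision_values
  if (is.null(dv)) stop("report carries no decision values", call. = FALSE)
  truth <- report$predictions$truth
  curves <- lapply(colnames(dv), function(cl) {
    roc_one_vs_rest(dv[, cl], truth, cl)
  })
  names(curves) <- colnames(dv)
  list(per_class = curves, macro = average_roc(curves, grid_size))
}

#' Write ROC points as TSV
#'
#' @param curve A `roc_curve`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_roc_tsv <- function(curve, path) {
  utils::write.table(curve$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
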