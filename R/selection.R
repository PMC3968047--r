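# Feature selection: multiclass SVM-RFE (one-at-a-time backward elimination
# with a linear-kernel squared-weight criterion summed over the one-vs-one
# binary machines) and the univariate F-score baseline.

#' Multiclass F-score of every feature
#'
#' For feature x, F = sum_c (xbar_c - xbar)^2 /
#' sum_c [ (1 / (n_c - 1)) * sum_(i in c) (x_i - xbar_c)^2 ].
#' Features with zero denominator (constant within every class) score 0.
#'
#' @param data Feature tibble (`protein_id`, `class`, feature columns).
#' @return Tibble with `feature`, `block`, `f_score`, sorted best-first.
#' @export
f_score <- function(data) {
  parts <- feature_matrix_parts(data)
  y <- droplevels(parts$y)
  if (nlevels(y) < 2) stop("F-score needs at least 2 classes", call. = FALSE)
  if (any(table(y) < 2)) stop("each class needs at least 2 samples", call. = FALSE)
  x <- parts$x
  overall <- colMeans(x)
  num <- rep(0, ncol(x)); den <- rep(0, ncol(x))
  for (cl in levels(y)) {
    xc <- x[y == cl, , drop = FALSE]
    m <- colMeans(xc)
    num <- num + (m - overall)^2
    den <- den + colSums(sweep(xc, 2, m)^2) / (nrow(xc) - 1)
  }
  s <- unname(ifelse(den > 0, num / den, 0))
  tibble::tibble(feature = parts$features,
                 block = feature_block(parts$features),
                 f_score = s) |>
    dplyr::arrange(dplyr::desc(.data$f_score))
}

# squared-weight criterion per feature: sum over all one-vs-one linear SVMs
# of w_f^2, fitted on (already standardized) x
ovo_weight_criterion <- function(x, y, cost) {
  lv <- levels(droplevels(y))
  crit <- rep(0, ncol(x))
  for (i in seq_len(length(lv) - 1)) {
    for (j in seq(i + 1, length(lv))) {
      sel <- y %in% c(lv[[i]], lv[[j]])
      fit <- e1071::svm(x[sel, , drop = FALSE], droplevels(y[sel]),
                        kernel = "linear", cost = cost, scale = FALSE)
      w <- crossprod(fit$coefs, fit$SV)
      crit <- crit + as.numeric(w)^2
    }
  }
  crit
}

#' Rank features by SVM-RFE
#'
#' Iteratively fits linear-kernel one-vs-one SVMs on the surviving features,
#' scores each feature by the sum of its squared weights over all binary
#' machines, and eliminates the single feature with the smallest score (ties
#' broken toward the lowest column index). Repeats until no features remain;
#' the last survivor is the top-ranked feature.
#'
#' Features are standardized once (zero mean, unit variance over the input
#' rows) before ranking, since weight magnitudes are scale-dependent;
#' constant features get zero weight by construction.
#'
#' @param data Feature tibble (`protein_id`, `class`, feature columns).
#' @param cost Linear-SVM regularization parameter C (default 1).
#' @param step Features eliminated per iteration. The method's definition is
#'   1; values > 1 are a documented speed deviation.
#' @param scale Standardize features before ranking (default TRUE).
#' @return Object of class `svm_rfe_ranking`: list with `rank_list`
#'   (best-first feature names), `elimination_order` (first-eliminated first),
#'   `criterion_trace` (criterion of each eliminated feature at its
#'   elimination), `features` (original column order) and `cost`.
#' @export
svm_rfe <- function(data, cost = 1, step = 1, scale = TRUE) {
  parts <- feature_matrix_parts(data)
  y <- droplevels(parts$y)
  if (nlevels(y) < 2) stop("SVM-RFE needs at least 2 classes", call. = FALSE)
  x <- parts$x
  if (scale) {
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    sdv[sdv == 0] <- 1
    x <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  }
  d <- ncol(x)
  surviving <- seq_len(d)
  eliminated <- integer(0)
  trace <- numeric(0)
  while (length(surviving) > 0) {
    if (length(surviving) == 1) {
      eliminated <- c(eliminated, surviving)
      trace <- c(trace, NA_real_)
      break
    }
    crit <- ovo_weight_criterion(x[, surviving, drop = FALSE], y, cost)
    k <- min(step, length(surviving) - 1)
    # ties -> lowest column index first (order() is stable)
    drop_pos <- order(crit)[seq_len(k)]
    eliminated <- c(eliminated, surviving[drop_pos])
    trace <- c(trace, crit[drop_pos])
    surviving <- surviving[-drop_pos]
  }
  structure(list(
    rank_list = parts$features[rev(eliminated)],
    elimination_order = parts$features[eliminated],
    criterion_trace = trace,
    features = parts$features,
    cost = cost,
    step = step
  ), class = "svm_rfe_ranking")
}

#' @export
print.svm_rfe_ranking <- function(x, ...) {
  cat("<svm_rfe_ranking> ", length(x$rank_list), " features; top 5: ",
      paste(utils::head(x$rank_list, 5), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
#' @importFrom generics tidy
#' @method tidy svm_rfe_ranking
#' @rdname svm_rfe
#' @param x,... For `tidy()`: a `svm_rfe_ranking` and ignored dots.
tidy.svm_rfe_ranking <- function(x, ...) {
  n <- length(x$rank_list)
  tibble::tibble(
    rank = seq_len(n),
    feature = x$rank_list,
    block = feature_block(x$rank_list),
    criterion = rev(x$criterion_trace)
  )
}

#' Restrict a feature tibble to the k best-ranked features
#'
#' @param data Feature tibble.
#' @param ranking A `svm_rfe_ranking` (or a character vector of feature names
#'   best-first).
#' @param k Number of top features to keep (1 <= k <= number ranked).
#' @return Feature tibble with `protein_id`, `class` and the top-k feature
#'   columns in rank order; attribute `block_composition` counts kept
#'   features per block.
#' @export
top_k <- function(data, ranking, k) {
  rank_list <- if (inherits(ranking, "svm_rfe_ranking")) ranking$rank_list else as.character(ranking)
  if (k < 1 || k > length(rank_list)) {
    stop("k must be between 1 and ", length(rank_list), call. = FALSE)
  }
  keep <- rank_list[seq_len(k)]
  missing_f <- setdiff(keep, names(data))
  if (length(missing_f) > 0) {
    stop("ranked feature(s) absent from data: ",
         paste(utils::head(missing_f, 5), collapse = ", "), call. = FALSE)
  }
  out <- data[, c(id_columns(), keep)]
  attr(out, "block_composition") <- table(factor(feature_block(keep),
    levels = c("pssm_lpc", "profeat", "go", "other")))
  out
}

#' Ranking as a TSV file
#'
#' Writes rank, feature name, block tag and criterion value.
#'
#' @param ranking A `svm_rfe_ranking`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path) {
  utils::write.table(tidy(ranking), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
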