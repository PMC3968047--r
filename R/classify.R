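# One-vs-one SVM classification (libsvm via e1071): training with stored
# scaling statistics, prediction with one-vs-rest decision values for ROC use,
# and grid search over the RBF (C, gamma) plane.

#' SVM parameters
#'
#' @param cost Regularization parameter C (> 0).
#' @param gamma RBF kernel width (> 0; ignored for linear kernel).
#' @param kernel `"radial"` or `"linear"`.
#' @return List of class `svm_params`.
#' @export
svm_params <- function(cost = 1, gamma = 1 / 16, kernel = c("radial", "linear")) {
  kernel <- match.arg(kernel)
  stopifnot(cost > 0, kernel == "linear" || gamma > 0)
  structure(list(cost = cost, gamma = gamma, kernel = kernel),
            class = "svm_params")
}

#' The canonical grid-search grids
#'
#' C over 2^(-5), 2^(-3), ..., 2^15 and gamma over 2^(-15), 2^(-13), ..., 2^3.
#'
#' @return List with `cost` and `gamma` numeric vectors.
#' @export
default_grids <- function() {
  list(cost = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2))
}

#' Train a one-vs-one SVM on a feature tibble
#'
#' Fits the k(k-1)/2 pairwise binary machines (libsvm's native multiclass
#' decomposition) on features standardized with statistics computed from the
#' training rows, and records everything needed to score new data with the
#' same feature list.
#'
#' @param data Feature tibble (`protein_id`, `class`, feature columns).
#' @param params An [svm_params()].
#' @return Object of class `structclass_model`.
#' @export
svm_train <- function(data, params = svm_params()) {
  stopifnot(inherits(params, "svm_params"))
  parts <- feature_matrix_parts(data)
  y <- droplevels(parts$y)
  if (nlevels(y) < 2) stop("training needs at least 2 classes", call. = FALSE)
  x <- parts$x
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  fit <- e1071::svm(xs, y, kernel = params$kernel, cost = params$cost,
                    gamma = params$gamma, scale = FALSE)
  structure(list(fit = fit, params = params, features = parts$features,
                 classes = levels(y), center = mu, scale = sdv),
            class = "structclass_model")
}

#' @export
print.structclass_model <- function(x, ...) {
  cat("<structclass_model> ", x$params$kernel, "-kernel one-vs-one SVM, ",
      length(x$classes), " classes, ", length(x$features), " features\n",
      sep = "")
  invisible(x)
}

# standardize new data with the model's training statistics
model_design <- function(object, newdata) {
  feats <- setdiff(names(newdata), id_columns())
  missing_f <- setdiff(object$features, feats)
  extra_f <- setdiff(feats, object$features)
  if (length(missing_f) > 0 || length(extra_f) > 0) {
    stop("feature mismatch at predict time",
         if (length(missing_f)) paste0("; missing: ",
           paste(utils::head(missing_f, 5), collapse = ", ")),
         if (length(extra_f)) paste0("; extra: ",
           paste(utils::head(extra_f, 5), collapse = ", ")),
         call. = FALSE)
  }
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  sweep(sweep(x, 2, object$center), 2, object$scale, "/")
}

#' Predict structural classes
#'
#' @param object A `structclass_model`.
#' @param newdata Feature tibble with exactly the training feature columns.
#' @param decision_values Also return the one-vs-one decision values and the
#'   per-class one-vs-rest aggregates.
#' @param ... Unused.
#' @return A factor of predicted classes; with `decision_values = TRUE`, a
#'   list with `class`, `ovo` (pairwise decision values) and `ovr`
#'   (per-class vote-margin aggregates used for ROC curves).
#' @export
predict.structclass_model <- function(object, newdata, decision_values = FALSE, ...) {
  xs <- model_design(object, newdata)
  pred <- predict(object$fit, xs, decision.values = decision_values)
  if (!decision_values) return(pred)
  dv <- attr(pred, "decision.values")
  list(class = factor(as.character(pred), levels = object$classes),
       ovo = dv,
       ovr = ovr_from_ovo(dv, object$classes))
}

# one-vs-rest score for class c = sum of c's signed margins over its
# one-vs-one machines (columns named "i/j", positive favours i). Class labels
# may themselves contain "/" (alpha/beta), so the pair name is split at the
# separator position where both halves are known class labels.
split_pair_name <- function(name, classes) {
  slash <- gregexpr("/", name, fixed = TRUE)[[1]]
  for (pos in slash) {
    i <- substr(name, 1, pos - 1)
    j <- substr(name, pos + 1, nchar(name))
    if (i %in% classes && j %in% classes) return(c(i, j))
  }
  stop("cannot resolve decision-value pair name: ", name, call. = FALSE)
}

ovr_from_ovo <- function(dv, classes) {
  out <- matrix(0, nrow = nrow(dv), ncol = length(classes),
                dimnames = list(rownames(dv), classes))
  for (k in seq_len(ncol(dv))) {
    pair <- split_pair_name(colnames(dv)[[k]], classes)
    out[, pair[[1]]] <- out[, pair[[1]]] + dv[, k]
    out[, pair[[2]]] <- out[, pair[[2]]] - dv[, k]
  }
  out
}

#' Grid search over (C, gamma)
#'
#' Evaluates every pair of the two grids by cross-validated (or jackknife,
#' i.e. leave-one-out) overall accuracy and returns the best parameters; ties
#' resolve toward smaller C, then smaller gamma.
#'
#' @param data Feature tibble.
#' @param cost_grid,gamma_grid Numeric grids (default [default_grids()]).
#' @param protocol `"cv"` (stratified k-fold) or `"jackknife"`.
#' @param folds Number of folds for `"cv"` (default 5).
#' @param kernel Kernel for all fits (default `"radial"`).
#' @param seed Integer seed controlling the fold assignment.
#' @return List with `best` (an [svm_params()]), `best_accuracy` and
#'   `table` (a tibble with one row per grid pair and its accuracy).
#' @export
grid_search <- function(data, cost_grid = default_grids()$cost,
                        gamma_grid = default_grids()$gamma,
                        protocol = c("cv", "jackknife"), folds = 5,
                        kernel = "radial", seed = 1) {
  protocol <- match.arg(protocol)
  stopifnot(length(cost_grid) > 0, length(gamma_grid) > 0)
  parts <- feature_matrix_parts(data)
  n <- nrow(parts$x)
  fold_id <- if (protocol == "jackknife") {
    seq_len(n)
  } else {
    withr::with_seed(seed, {
      id <- integer(n)
      for (cl in levels(droplevels(parts$y))) {
        idx <- sample(which(parts$y == cl))
        id[idx] <- rep_len(seq_len(folds), length(idx))
      }
      id
    })
  }
  grid <- tidyr::expand_grid(cost = cost_grid, gamma = gamma_grid)
  acc <- purrr::map2_dbl(grid$cost, grid$gamma, function(C, g) {
    params <- svm_params(C, g, kernel)
    correct <- 0L
    for (f in sort(unique(fold_id))) {
      tr <- data[fold_id != f, , drop = FALSE]
      te <- data[fold_id == f, , drop = FALSE]
      if (nlevels(droplevels(as_class_factor(tr$class))) < 2) {
        stop("a fold lost all but one class; use more samples or fewer folds",
             call. = FALSE)
      }
      model <- svm_train(tr, params)
      correct <- correct + sum(predict(model, te) == te$class)
    }
    correct / n
  })
  tab <- dplyr::mutate(grid, accuracy = acc)
  best_row <- tab |>
    dplyr::arrange(dplyr::desc(.data$accuracy), .data$cost, .data$gamma) |>
    dplyr::slice(1)
  list(best = svm_params(best_row$cost, best_row$gamma, kernel),
       best_accuracy = best_row$accuracy,
       table = tab)
}
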