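test_that("a feature identical in all samples has F-score 0", {
  data <- make_blob_data(n_per_class = 4)
  data$feat_6 <- 1
  fs <- f_score(data)
  expect_equal(fs$f_score[fs$feature == "feat_6"], 0)
})

test_that("zero within-class variance hits the 0-denominator convention", {
  data <- make_blob_data(n_per_class = 4)
  data$feat_5 <- as.numeric(data$class == "all-alpha")  # exact class indicator
  fs0 <- f_score(data)
  expect_equal(fs0$f_score[fs0$feature == "feat_5"], 0)
  # with a little noise the same feature dominates
  data$feat_5 <- data$feat_5 + withr::with_seed(1, rnorm(nrow(data), sd = 1e-3))
  fs1 <- f_score(data)
  expect_equal(fs1$feature[[1]], "feat_5")
})

test_that("a planted shifted feature attains the maximum F-score", {
  withr::with_seed(33, {
    n <- 40
    cls <- rep(structural_classes(), each = 10)
    x <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
    x[, 3] <- x[, 3] + 4 * as.numeric(factor(cls))
    data <- dplyr::bind_cols(
      tibble::tibble(protein_id = as.character(1:n), class = cls),
      tibble::as_tibble(x))
  })
  fs <- f_score(data)
  expect_equal(fs$feature[[1]], "f3")
  # cross-check the formula directly for the planted feature
  y <- factor(data$class)
  xf <- data$f3
  num <- sum((tapply(xf, y, mean) - mean(xf))^2)
  den <- sum(tapply(xf, y, function(v) sum((v - mean(v))^2) / (length(v) - 1)))
  expect_equal(fs$f_score[fs$feature == "f3"], num / den)
})

test_that("single-class input is rejected", {
  data <- make_blob_data(n_per_class = 3)
  expect_error(f_score(data[data$class == "all-alpha", ]), "2 classes")
  expect_error(svm_rfe(data[data$class == "all-alpha", ]), "2 classes")
})

test_that("single-feature ranking is trivial", {
  data <- make_blob_data(n_per_class = 3, n_features = 1)
  rk <- svm_rfe(data)
  expect_identical(rk$rank_list, "feat_1")
  expect_identical(rk$elimination_order, "feat_1")
})

test_that("a constant feature is eliminated before a separating one", {
  withr::with_seed(34, {
    cls <- rep(structural_classes()[1:2], each = 8)
    data <- tibble::tibble(
      protein_id = as.character(1:16),
      class = cls,
      separating = ifelse(cls == "all-alpha", 1, -1) + rnorm(16, sd = 0.05),
      constant = 1
    )
  })
  rk <- svm_rfe(data)
  expect_identical(rk$elimination_order[[1]], "constant")
  expect_identical(rk$rank_list[[1]], "separating")
})

test_that("rank_list and elimination_order are mutually reversed permutations", {
  data <- make_blob_data(n_per_class = 4, n_features = 7, seed = 35)
  rk <- svm_rfe(data)
  expect_setequal(rk$rank_list, paste0("feat_", 1:7))
  expect_identical(rk$rank_list, rev(rk$elimination_order))
  td <- tidy(rk)
  expect_identical(td$rank, 1:7)
  expect_identical(td$feature, rk$rank_list)
})

test_that("first-iteration criterion equals squared weights of a single fit", {
  withr::with_seed(36, {
    cls <- rep(structural_classes()[1:2], each = 10)
    x <- matrix(rnorm(20 * 5), 20, 5, dimnames = list(NULL, paste0("f", 1:5)))
    x[cls == "all-alpha", 1] <- x[cls == "all-alpha", 1] + 2
    data <- dplyr::bind_cols(
      tibble::tibble(protein_id = as.character(1:20), class = cls),
      tibble::as_tibble(x))
  })
  rk <- svm_rfe(data, cost = 1, scale = FALSE)
  # independent single fit with identical solver settings
  fit <- e1071::svm(x, factor(cls), kernel = "linear", cost = 1, scale = FALSE)
  w2 <- as.numeric(crossprod(fit$coefs, fit$SV))^2
  # the first eliminated feature carries the smallest w^2 and matches its value
  first <- rk$elimination_order[[1]]
  expect_equal(rk$criterion_trace[[1]], unname(w2[[match(first, paste0("f", 1:5))]]),
               tolerance = 1e-10)
  expect_equal(first, paste0("f", which.min(w2)))
})

test_that("an informative feature among pure noise is ranked first", {
  hits <- 0
  for (seed in 1:25) {
    withr::with_seed(200 + seed, {
      cls <- rep(structural_classes()[1:2], each = 10)
      x <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("f", 1:6)))
      x[, 4] <- x[, 4] + ifelse(cls == "all-alpha", 2.5, -2.5)
      data <- dplyr::bind_cols(
        tibble::tibble(protein_id = as.character(1:20), class = cls),
        tibble::as_tibble(x))
    })
    rk <- svm_rfe(data)
    hits <- hits + (rk$rank_list[[1]] == "f4")
  }
  expect_gte(hits / 25, 0.95)
})

test_that("top_k restricts, preserves names and reports block composition", {
  data <- make_blob_data(n_per_class = 3, n_features = 5, seed = 37)
  rk <- svm_rfe(data)
  full <- top_k(data, rk, 5)
  expect_setequal(setdiff(names(full), id_columns()), paste0("feat_", 1:5))
  one <- top_k(data, rk, 1)
  expect_identical(setdiff(names(one), id_columns()), rk$rank_list[[1]])
  expect_error(top_k(data, rk, 0), "between 1 and")
  expect_error(top_k(data, rk, 6), "between 1 and")
  comp <- attr(top_k(data, rk, 3), "block_composition")
  expect_equal(sum(comp), 3)
})

test_that("planted informative features are recovered in a top-k window", {
  spec <- synthetic_spec(n_per_class = c(8, 8, 8, 8), seed = 38)
  d <- generate_synthetic_dataset(spec)
  feats <- extract_features(d$manifest, d$sequences, d$pssms, d$annotations,
                           lpc_orders = lpc_config(3L),
                           preset = descriptor_preset(groups = "aac"))
  rk <- svm_rfe(feats)
  planted <- planted_feature_names(d$ground_truth, 3L)
  window <- rk$rank_list[seq_len(2 * length(planted))]
  expect_gte(sum(planted %in% window) / length(planted), 0.8)
})

test_that("ranking TSV round-trips through tidy()", {
  data <- make_blob_data(n_per_class = 3, n_features = 4, seed = 39)
  rk <- svm_rfe(data)
  path <- tempfile(fileext = ".tsv")
  write_ranking_tsv(rk, path)
  df <- utils::read.delim(path)
  expect_identical(df$feature, rk$rank_list)
  expect_identical(names(df), c("rank", "feature", "block", "criterion"))
})
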