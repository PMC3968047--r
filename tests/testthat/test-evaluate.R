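test_that("MCC hits its closed-form anchor points", {
  expect_equal(mcc_from_counts(10, 0, 10, 0), 1)
  expect_equal(mcc_from_counts(0, 10, 0, 10), -1)
  expect_equal(mcc_from_counts(0, 0, 5, 0), 0)  # zero-denominator convention
})

test_that("MCC equals the Pearson correlation of the binary vectors", {
  tp <- 5; fp <- 3; tn <- 7; fn <- 2
  truth <- c(rep(1, tp + fn), rep(0, fp + tn))
  pred <- c(rep(1, tp), rep(0, fn), rep(1, fp), rep(0, tn))
  expect_equal(mcc_from_counts(tp, fp, tn, fn), cor(truth, pred))
})

test_that("MCC is symmetric under TP<->TN, FP<->FN swap", {
  withr::with_seed(51, {
    for (i in 1:20) {
      cnt <- sample(0:30, 4, replace = TRUE)
      expect_equal(mcc_from_counts(cnt[1], cnt[2], cnt[3], cnt[4]),
                   mcc_from_counts(cnt[3], cnt[4], cnt[1], cnt[2]))
    }
  })
})

test_that("confusion matrix uses the fixed class order and sums to N", {
  truth <- c("all-alpha", "all-beta", "alpha/beta", "alpha+beta", "all-alpha")
  pred <- c("all-alpha", "all-alpha", "alpha/beta", "alpha+beta", "all-beta")
  cm <- confusion_matrix(truth, pred)
  expect_identical(rownames(cm), structural_classes())
  expect_equal(sum(cm), 5)
  expect_equal(cm["all-alpha", "all-beta"], 1L, ignore_attr = TRUE)
})

test_that("report identities hold: trace accuracy and weighted per-class sum", {
  withr::with_seed(52, {
    truth <- sample(structural_classes(), 60, replace = TRUE)
    pred <- ifelse(runif(60) < 0.6, truth,
                   sample(structural_classes(), 60, replace = TRUE))
  })
  rep_ <- evaluation_report(truth, pred)
  expect_equal(rep_$overall_accuracy, sum(diag(rep_$confusion)) / 60)
  w <- rowSums(rep_$confusion) / 60
  expect_equal(sum(rep_$per_class$accuracy * w), rep_$overall_accuracy)
  expect_true(all(rep_$per_class$mcc >= -1 & rep_$per_class$mcc <= 1))
  g <- glance(rep_)
  expect_equal(g$overall_accuracy, rep_$overall_accuracy)
})

test_that("perfect predictions give accuracy 1 and all MCC 1", {
  truth <- rep(structural_classes(), each = 5)
  rep_ <- evaluation_report(truth, truth)
  expect_equal(rep_$overall_accuracy, 1)
  expect_true(all(rep_$per_class$accuracy == 1))
  expect_true(all(rep_$per_class$mcc == 1))
})

test_that("randomly permuted labels give near-zero MCC on average", {
  truth <- rep(structural_classes()[1:2], each = 20)
  mccs <- withr::with_seed(53, {
    vapply(1:50, function(i) {
      mean(evaluation_report(sample(truth), truth)$per_class$mcc)
    }, numeric(1))
  })
  expect_lt(abs(mean(mccs)), 0.15)
})

test_that("jackknife on separable 4-class data is perfect and runs N rounds", {
  data <- make_blob_data(n_per_class = 4, shift = 8, seed = 54)
  rep_ <- jackknife(data, svm_params(cost = 8, gamma = 0.02))
  expect_equal(rep_$n, nrow(data))
  expect_equal(nrow(rep_$predictions), nrow(data))
  expect_equal(rep_$overall_accuracy, 1)
  expect_true(all(rep_$per_class$mcc == 1))
  expect_equal(dim(rep_$decision_values), c(nrow(data), 4))
  expect_true(all(is.finite(rep_$decision_values)))
})

test_that("jackknife rejects datasets where a fold would lose a class", {
  data <- make_blob_data(n_per_class = 3, seed = 55)
  solo <- data[c(which(data$class == "all-alpha")[1],
                 which(data$class != "all-alpha")), ]
  expect_error(jackknife(solo, svm_params()), "lose an entire class")
})

test_that("rank-once jackknife with internal ranking truncates once", {
  data <- make_blob_data(n_per_class = 4, shift = 6, seed = 56)
  rep_ <- jackknife(data, svm_params(cost = 8, gamma = 0.02),
                    protocol = "rank_once", k = 4)
  expect_equal(rep_$overall_accuracy, 1)
})

test_that("nested protocol re-ranks inside each fold", {
  data <- make_blob_data(n_per_class = 3, n_features = 5, shift = 6, seed = 57)
  rep_ <- jackknife(data, svm_params(cost = 8, gamma = 0.02),
                    protocol = "nested", k = 4)
  expect_equal(rep_$n, nrow(data))
  expect_gte(rep_$overall_accuracy, 0.9)
})

test_that("report JSON serialization carries the confusion and metrics", {
  data <- make_blob_data(n_per_class = 3, shift = 8, seed = 58)
  rep_ <- jackknife(data, svm_params(cost = 8, gamma = 0.02))
  jp <- tempfile(fileext = ".json"); tp <- tempfile(fileext = ".tsv")
  write_report(rep_, jp, tp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$n, rep_$n)
  expect_equal(back$overall_accuracy, rep_$overall_accuracy)
  preds <- utils::read.delim(tp)
  expect_equal(nrow(preds), rep_$n)
})
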