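test_that("balanced accuracy is the mean of per-class recalls", {
  # majority-only predictor over 3 classes
  truth <- rep(c("a", "n", "v"), c(70, 20, 10))
  pred <- rep("a", 100)
  expect_equal(balanced_accuracy(confusion_matrix(truth, pred)), 1 / 3)
  expect_equal(balanced_accuracy(diag(5)), 1)
  cm <- matrix(c(8, 4, 2, 6), 2)  # recalls 0.8 and 0.6
  expect_equal(balanced_accuracy(cm), 0.7)
  empty <- matrix(c(3, 0, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(balanced_accuracy(empty), "zero support")
})

test_that("per-class metrics match hand arithmetic and conventions", {
  cm <- matrix(c(8, 4, 2, 6), 2, dimnames = list(c("p", "q"), c("p", "q")))
  m <- per_class_metrics(cm)
  expect_equal(m$per_class$precision[1], 8 / 12)
  expect_equal(m$per_class$recall[1], 0.8)
  expect_equal(m$per_class$f1[1], 2 * (2 / 3 * 0.8) / (2 / 3 + 0.8))
  expect_equal(m$accuracy, 14 / 20)

  perfect <- per_class_metrics(diag(3) * 5)
  expect_true(all(perfect$per_class[, c("precision", "recall", "f1")] == 1))

  never <- matrix(c(5, 3, 0, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(mn <- per_class_metrics(never), "never predicted")
  expect_equal(mn$per_class$precision[2], 0)
  expect_equal(mn$per_class$f1[2], 0)
})

test_that("support-weighted recall equals plain accuracy", {
  set.seed(17)
  for (i in 1:15) {
    k <- sample(2:6, 1)
    cm <- matrix(rpois(k * k, 8) + 1, k,
                 dimnames = list(letters[1:k], letters[1:k]))
    m <- per_class_metrics(cm)
    expect_equal(unname(m$weighted["recall"]), m$accuracy)
  }
})

test_that("stratified folds keep per-class counts within one of exact", {
  labels <- rep(c("rare", "mid", "big"), c(156, 844, 4000))
  plan <- make_splits(labels, protocol = "stratified_kfold", k = 5, seed = 2)
  expect_identical(sort(unique(plan$fold)), 1:5)
  for (cl in unique(labels)) {
    per_fold <- table(plan$fold[labels == cl])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  # the 156-sample class lands 31 or 32 per fold
  rare <- table(plan$fold[labels == "rare"])
  expect_true(all(rare %in% c(31, 32)))
  expect_warning(make_splits(rep(c("a", "b"), c(3, 100)), k = 5, seed = 1),
                 "fewer samples")
})

test_that("grouped folds never split a video and lovo makes one fold per video", {
  set.seed(6)
  videos <- rep(sprintf("v%02d", 1:28), each = 30)
  labels <- sample(behavior_parents(), length(videos), TRUE)
  g <- make_splits(labels, videos, protocol = "grouped_kfold", k = 5, seed = 3)
  for (v in unique(videos)) {
    expect_length(unique(g$fold[videos == v]), 1)
  }
  expect_identical(sort(unique(g$fold)), 1:5)
  l <- make_splits(labels, videos, protocol = "lovo")
  expect_identical(l$k, 28L)
  expect_identical(length(unique(l$fold)), 28L)
  expect_error(make_splits(labels, protocol = "grouped_kfold"), "video_ids")
})

test_that("cross-validated predictions cover every sample exactly once", {
  d <- separable_data(n_per = 18)
  plan <- make_splits(d$y, protocol = "stratified_kfold", k = 3, seed = 4)
  seen_scalers <- list()
  factory <- function(xtr, ytr, fold) {
    m <- equiboost(xtr, ytr, learner = learner_rpart())
    seen_scalers[[length(seen_scalers) + 1]] <<- m$scaler$median
    m
  }
  cv <- cross_val_predict(d$x, d$y, plan, factory,
                          function(m, x) as.character(predict(m, x)))
  expect_false(any(cv$predictions == ""))
  expect_identical(cv$predictions, d$y)  # separable: perfect out-of-fold
  expect_length(cv$fold_scores, 3)
  expect_equal(cv$fold_scores, rep(1, 3))
  # leakage guard: scaler statistics are refit per training fold
  expect_gt(length(unique(vapply(seen_scalers, paste, collapse = ",",
                                 FUN.VALUE = ""))), 1)
})

test_that("Wilson intervals match the closed form and stay in [0, 1]", {
  z <- stats::qnorm(0.975)
  ci <- wilson_ci(0, 10)
  expect_equal(unname(ci), c(0, z^2 / (10 + z^2)), tolerance = 1e-12)
  ci2 <- wilson_ci(10, 10)
  expect_equal(unname(ci2[2]), 1)
  expect_equal(unname(ci2[1]), 1 - z^2 / (10 + z^2), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    n <- sample(1:500, 1)
    s <- sample(0:n, 1)
    ci <- wilson_ci(s, n)
    expect_gte(ci[[1]], 0); expect_lte(ci[[2]], 1)
    expect_gte(s / n, ci[[1]]); expect_lte(s / n, ci[[2]])
  }
})

test_that("McNemar statistic matches direct arithmetic and stats::mcnemar.test", {
  expect_equal(mcnemar_test(7, 7)$statistic, 0)
  expect_equal(mcnemar_test(10, 0)$statistic, 10)
  expect_equal(mcnemar_test(15, 5)$statistic, 5)
  ref <- stats::mcnemar.test(matrix(c(30, 5, 15, 40), 2), correct = FALSE)
  ours <- mcnemar_test(15, 5)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)
  refc <- stats::mcnemar.test(matrix(c(30, 5, 15, 40), 2), correct = TRUE)
  expect_equal(mcnemar_test(15, 5, correction = TRUE)$statistic,
               unname(refc$statistic))
  expect_warning(z <- mcnemar_test(0, 0), "no discordant")
  expect_equal(z$statistic, 0)
})

test_that("paired fold test matches t.test and flags degenerate differences", {
  a <- c(0.7, 0.8, 0.75, 0.82, 0.78)
  b <- c(0.6, 0.72, 0.70, 0.71, 0.69)
  ours <- paired_fold_test(a, b)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)
  expect_false(ours$degenerate)

  # differences (2, 3, 4): t = 3 sqrt(3)
  d <- paired_fold_test(c(2, 3, 4), c(0, 0, 0))
  expect_equal(d$statistic, 3 * sqrt(3), tolerance = 1e-12)

  same <- paired_fold_test(a, a)
  expect_true(same$degenerate)
  expect_equal(same$statistic, 0)
  const <- paired_fold_test(a + 0.05, a)
  expect_true(const$degenerate)
  expect_identical(const$statistic, Inf)
})

test_that("one-vs-rest AUC and AP match brute force and pROC", {
  # 4-sample worked case: 3 wins of 4 positive-negative pairs
  labels <- c("pos", "neg", "pos", "neg")
  probs <- cbind(pos = c(0.9, 0.8, 0.7, 0.1))
  probs <- cbind(probs, neg = 1 - probs[, 1])
  res <- ovr_curves(labels, probs)
  expect_equal(res$auc[res$class == "pos"], 0.75)

  # brute-force pairwise oracle on random scores
  set.seed(12)
  lab <- sample(c("pos", "neg"), 80, TRUE)
  s <- runif(80)
  pr <- cbind(pos = s, neg = 1 - s)
  brute <- {
    sp <- s[lab == "pos"]; sn <- s[lab == "neg"]
    mean(outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  got <- ovr_curves(lab, pr)
  expect_equal(got$auc[got$class == "pos"], brute)
  expect_equal(got$auc[got$class == "pos"],
               as.numeric(pROC::auc(pROC::roc(lab == "pos", s, quiet = TRUE))))

  # perfect ranking
  perf <- ovr_curves(c("pos", "pos", "neg"),
                     cbind(pos = c(0.9, 0.8, 0.2), neg = c(0.1, 0.2, 0.8)))
  expect_equal(perf$auc[perf$class == "pos"], 1)
  expect_equal(perf$average_precision[perf$class == "pos"], 1)

  # random scores on balanced labels hover near 0.5
  set.seed(13)
  lab2 <- rep(c("pos", "neg"), 2500)
  s2 <- runif(5000)
  r2 <- ovr_curves(lab2, cbind(pos = s2, neg = 1 - s2))
  expect_lt(abs(r2$auc[r2$class == "pos"] - 0.5), 0.05)

  expect_error(ovr_curves(rep("pos", 4), probs), "single-class")
})
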