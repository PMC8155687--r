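test_that("fold plans stratify by round-robin dealing", {
  # exact divisibility: 5/5 samples into 5 folds -> one of each class per fold
  y <- factor(rep(c("a", "b"), each = 5))
  plan <- make_fold_plan(y, n_folds = 5, n_repeats = 3, seed = 2)
  for (r in 1:3) {
    tab <- table(y, plan$assignment[, r])
    expect_true(all(tab == 1))
  }

  # 40/22 into 10 folds: class sizes {4}x10 and {2 or 3} summing to 22
  y2 <- factor(rep(c("a", "b"), c(40, 22)))
  plan2 <- make_fold_plan(y2, seed = 9)
  for (r in seq_len(plan2$n_repeats)) {
    tab <- table(y2, plan2$assignment[, r])
    expect_true(all(tab["a", ] == 4))
    expect_true(all(tab["b", ] %in% 2:3))
    expect_identical(sum(tab["b", ]), 22L)
  }

  # a class smaller than the fold count is spread over distinct folds
  y3 <- factor(rep(c("a", "b"), c(30, 4)))
  plan3 <- make_fold_plan(y3, seed = 1)
  for (r in seq_len(plan3$n_repeats)) {
    small <- plan3$assignment[y3 == "b", r]
    expect_identical(anyDuplicated(small), 0L)
  }
})

test_that("fold plans are deterministic and partition the samples exactly", {
  y <- factor(rep(c("a", "b", "c"), c(13, 8, 21)))
  p1 <- make_fold_plan(y, seed = 42)
  p2 <- make_fold_plan(y, seed = 42)
  expect_identical(p1$assignment, p2$assignment)
  for (r in seq_len(p1$n_repeats)) {
    expect_true(all(p1$assignment[, r] %in% 1:10))
    expect_false(anyNA(p1$assignment[, r]))
  }
  expect_error(make_fold_plan(factor(c("a", "b")), n_folds = 10),
               "more folds")
})

test_that("binary F2 matches its closed form and stays within bounds", {
  expect_equal(f2_binary(1, 1), 1)
  expect_equal(f2_binary(0.5, 0.5), 0.5)
  expect_equal(f2_binary(0.8, 0.6), 2 * 0.48 / 1.4)
  expect_equal(f2_binary(0, 0), 0)
  set.seed(3)
  for (rep in 1:200) {
    p <- stats::runif(1)
    np <- stats::runif(1)
    f2 <- f2_binary(p, np)
    expect_equal(f2, f2_binary(np, p))  # symmetric
    expect_gte(f2, 0)
    expect_lte(f2, 1)
    expect_lte(f2, 2 * min(p, np))
  }
})

test_that("multiclass F2 reduces to the binary form at l = 2 and matches
           the literal pairwise oracle at l = 3", {
  set.seed(14)
  for (rep in 1:1000) {
    truth <- factor(sample(c("a", "b"), 20, replace = TRUE,
                           prob = c(0.7, 0.3)), levels = c("a", "b"))
    pred <- factor(sample(c("a", "b"), 20, replace = TRUE),
                   levels = c("a", "b"))
    cm <- confusion_summary(truth, pred)
    tp <- cm["a", "a"]; fp <- cm["b", "a"]
    tn <- cm["b", "b"]; fn <- cm["a", "b"]
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    np <- if (tn + fn == 0) 0 else tn / (tn + fn)
    expect_equal(f2_multiclass(cm), f2_binary(p, np))
  }
  set.seed(15)
  for (rep in 1:50) {
    classes <- c("a", "b", "c")
    truth <- factor(sample(classes, 30, replace = TRUE), levels = classes)
    pred <- factor(sample(classes, 30, replace = TRUE), levels = classes)
    expect_equal(f2_multiclass(confusion_summary(truth, pred)),
                 oracle_f2_multiclass(truth, pred, classes))
  }
})

test_that("sensitivity and specificity come out of the counts", {
  # TP=9, FN=1, TN=4, FP=1 with 'pos' the first level
  truth <- factor(rep(c("pos", "neg"), c(10, 5)), levels = c("pos", "neg"))
  pred <- factor(c(rep("pos", 9), "neg", "pos", rep("neg", 4)),
                 levels = c("pos", "neg"))
  ss <- sensitivity_specificity(confusion_summary(truth, pred))
  expect_equal(unname(ss["sensitivity"]), 0.9)
  expect_equal(unname(ss["specificity"]), 0.8)

  # degenerate all-positive prediction: Sen 1, Spe 0, F2 0
  all_pos <- factor(rep("pos", 15), levels = c("pos", "neg"))
  cm <- confusion_summary(truth, all_pos)
  ss2 <- sensitivity_specificity(cm)
  expect_equal(unname(ss2["sensitivity"]), 1)
  expect_equal(unname(ss2["specificity"]), 0)
  expect_equal(f2_multiclass(cm), 0)

  # perfect classifier
  ss3 <- sensitivity_specificity(confusion_summary(truth, truth))
  expect_equal(unname(ss3), c(1, 1))
})

test_that("rank AUC counts pairs with ties at half", {
  lab <- factor(c("p", "n", "p"), levels = c("p", "n"))
  expect_equal(rank_auc(c(0.9, 0.8, 0.3), lab), 0.5)
  expect_equal(rank_auc(c(0.9, 0.1, 0.8), lab), 1)
  expect_equal(rank_auc(c(0.5, 0.5, 0.5), lab), 0.5)
  set.seed(21)
  for (rep in 1:50) {
    sc <- sample(seq(0, 1, 0.1), 12, replace = TRUE)
    is_pos <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    if (!any(is_pos) || all(is_pos)) next
    truth <- factor(ifelse(is_pos, "p", "n"), levels = c("p", "n"))
    expect_equal(rank_auc(sc, truth), oracle_auc(sc, is_pos))
  }
})

test_that("multiclass AUC averages pairwise AUCs and skips absent classes", {
  set.seed(22)
  mc <- generate_multiclass(sizes = c(12, 9, 6), d = 10, n_informative = 4,
                            offset = 6, seed = 5)
  # scores from a KNN fit on the data itself: sanity range
  cls <- knn_classifier()
  model <- cls$fit(mc$x, mc$y)
  pred <- cls$predict(model, mc$x)
  mauc <- multiclass_auc(pred$scores, mc$y)
  expect_gte(mauc, 0.9)
  expect_lte(mauc, 1)
  # perfectly separated per-class scores give exactly 1
  sc <- stats::model.matrix(~ mc$y - 1)
  colnames(sc) <- levels(mc$y)
  expect_equal(multiclass_auc(sc, mc$y), 1)
  # a pair missing one class is skipped, not NaN
  y_sub <- factor(rep(c("c1", "c2"), c(5, 5)), levels = c("c1", "c2", "c3"))
  sc_sub <- matrix(stats::runif(30), 10, 3,
                   dimnames = list(NULL, c("c1", "c2", "c3")))
  expect_false(is.na(multiclass_auc(sc_sub, y_sub)))
})

test_that("KNN adapter is deterministic and votes by the 5 nearest", {
  xtr <- rbind(matrix(0, 5, 2), matrix(10, 5, 2))
  ytr <- factor(rep(c("lo", "hi"), each = 5))
  cls <- knn_classifier()
  model <- cls$fit(xtr, ytr)
  out <- cls$predict(model, rbind(c(0.1, 0), c(9.8, 10)))
  expect_identical(as.character(out$class), c("lo", "hi"))
  expect_equal(unname(out$scores[1, "lo"]), 1)
  expect_equal(unname(out$scores[2, "hi"]), 1)
})

test_that("cross-validation attains perfect accuracy on separable data and
           averages metric records correctly", {
  mc <- generate_multiclass(sizes = c(15, 15), d = 20, n_informative = 5,
                            offset = 10, seed = 77)
  plan <- make_fold_plan(mc$y, n_folds = 5, n_repeats = 2, seed = 7)
  rec <- run_cv(mc$x, mc$y, plan, variant = "scefs", k_grid = 20,
                classifier = knn_classifier())
  acc <- rec$value[rec$metric == "acc"]
  expect_equal(mean(acc), 1)
  summ <- summarize_cv(rec)
  expect_equal(summ$mean[summ$metric == "acc"], 1)
  # one row per (k, metric); fold means invariant to record order
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(summarize_cv(shuffled)$mean, summ$mean)
})

test_that("feature selection is recomputed inside each training fold", {
  # f1's variance is produced by a single extreme sample; whether f1 wins
  # the ranking depends on that sample being inside the training fold
  set.seed(30)
  x <- cbind(f1 = c(50, rnorm(19, sd = 0.1)),
             f2 = rnorm(20, sd = 2),
             f3 = rnorm(20, sd = 0.5))
  rownames(x) <- paste0("s", 1:20)
  with_outlier <- select_features(x, 1, "scefs")$selected
  without <- select_features(x[-1, ], 1, "scefs")$selected
  expect_identical(with_outlier, "f1")
  expect_identical(without, "f2")
})

test_that("the linear SVM adapter separates an easy binary problem", {
  mc <- generate_multiclass(sizes = c(12, 12), d = 8, n_informative = 4,
                            offset = 8, seed = 11)
  plan <- make_fold_plan(mc$y, n_folds = 4, n_repeats = 1, seed = 3)
  rec <- run_cv(mc$x, mc$y, plan, variant = "scafs", k_grid = 4,
                classifier = svm_classifier())
  expect_equal(mean(rec$value[rec$metric == "acc"]), 1)
  expect_equal(mean(rec$value[rec$metric == "auc"]), 1)
})
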