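test_that("confusion matrix matches an independent tally on random labels", {
  withr_seed(19)
  truth <- sample(ploidy_classes(), 50, replace = TRUE)
  pred <- sample(ploidy_classes(), 50, replace = TRUE)
  cm <- confusion_matrix(truth, pred)
  for (i in seq_along(ploidy_classes())) {
    for (j in seq_along(ploidy_classes())) {
      n <- sum(truth == ploidy_classes()[i] & pred == ploidy_classes()[j])
      expect_identical(unname(cm[i, j]), as.integer(n))
    }
  }
  expect_equal(sum(cm), 50)
  expect_error(confusion_matrix(character(0), character(0)), "empty")
  expect_error(confusion_matrix(truth, pred[-1]), "length")
  expect_error(confusion_matrix(c("diploid"), c("triploid")), "class set")
})

test_that("one-vs-rest counts partition the matrix for every class", {
  cm <- confusion_matrix(
    rep(ploidy_classes(), times = c(4, 3, 5)),
    c("diploid", "diploid", "mixoploid", "tetraploid",
      "mixoploid", "diploid", "mixoploid",
      "tetraploid", "tetraploid", "tetraploid", "diploid", "mixoploid")
  )
  # manual tallies for the hand-built matrix
  expect_identical(per_class_counts(cm, "diploid"),
                   c(TP = 2L, FP = 2L, FN = 2L, TN = 6L))
  for (cl in ploidy_classes()) {
    expect_equal(sum(per_class_counts(cm, cl)), sum(cm))
  }
  # diagonal matrix: no false positives or negatives anywhere
  perfect <- confusion_matrix(rep(ploidy_classes(), 3),
                              rep(ploidy_classes(), 3))
  for (cl in ploidy_classes()) {
    ct <- per_class_counts(perfect, cl)
    expect_identical(unname(ct[c("FP", "FN")]), c(0L, 0L))
  }
})

test_that("metrics reproduce exact fractions and the perfect case", {
  # 55 of 57 correct: accuracy 96.4912%, error 3.5088%
  truth <- rep(ploidy_classes(), each = 19)
  pred <- truth
  pred[1] <- "mixoploid"; pred[20] <- "tetraploid"
  r <- compute_metrics(confusion_matrix(truth, pred))
  expect_equal(round(r$accuracy, 4), 96.4912)
  expect_equal(round(r$error_rate, 4), 3.5088)
  expect_equal(r$accuracy, 55 / 57 * 100)

  p <- compute_metrics(confusion_matrix(truth, truth))
  expect_equal(p$accuracy, 100)
  expect_equal(p$error_rate, 0)
  expect_equal(c(p$precision, p$recall, p$f1), c(1, 1, 1))
})

test_that("accuracy and error rate are complementary and order-free", {
  withr_seed(23)
  for (i in 1:200) {
    truth <- sample(ploidy_classes(), 30, replace = TRUE)
    pred <- sample(ploidy_classes(), 30, replace = TRUE)
    cm <- confusion_matrix(truth, pred)
    r <- compute_metrics(cm)
    expect_equal(r$accuracy + r$error_rate, 100)
    expect_within(c(r$precision, r$recall, r$f1), 0, 1)
    # F1 lies between precision and recall
    expect_gte(r$f1 + 1e-12, min(r$precision, r$recall))
    expect_lte(r$f1 - 1e-12, max(r$precision, r$recall))
    # permuting the class ordering leaves macro metrics unchanged
    perm <- c("tetraploid", "diploid", "mixoploid")
    r2 <- compute_metrics(confusion_matrix(truth, pred, classes = perm))
    expect_equal(r2$precision, r$precision)
    expect_equal(r2$recall, r$recall)
    expect_equal(r2$accuracy, r$accuracy)
  }
})

test_that("micro-averaged precision and recall equal the accuracy", {
  withr_seed(29)
  for (i in 1:50) {
    truth <- sample(ploidy_classes(), 40, replace = TRUE)
    pred <- sample(ploidy_classes(), 40, replace = TRUE)
    cm <- confusion_matrix(truth, pred)
    cts <- sapply(ploidy_classes(), function(cl) per_class_counts(cm, cl))
    micro_p <- sum(cts["TP", ]) / sum(cts["TP", ] + cts["FP", ])
    micro_r <- sum(cts["TP", ]) / sum(cts["TP", ] + cts["FN", ])
    acc <- compute_metrics(cm)$accuracy / 100
    expect_equal(micro_p, acc)
    expect_equal(micro_r, acc)
  }
})

test_that("F1 equals precision when precision equals recall", {
  withr_seed(31)
  for (i in 1:500) {
    # symmetric confusion matrices have equal macro precision and recall
    a <- sample(0:8, 1); b <- sample(0:8, 1); c <- sample(0:8, 1)
    m <- matrix(c(sample(1:9, 1), a, b,
                  a, sample(1:9, 1), c,
                  b, c, sample(1:9, 1)), 3, 3,
                dimnames = list(ploidy_classes(), ploidy_classes()))
    cm <- structure(m, class = c("confusion_matrix", "matrix", "array"))
    r <- compute_metrics(cm)
    expect_equal(r$precision, r$recall)
    expect_equal(r$f1, r$precision)
  }
})

test_that("a never-predicted class contributes zero precision", {
  truth <- c("diploid", "diploid", "mixoploid", "tetraploid")
  pred <- c("diploid", "diploid", "diploid", "diploid")
  r <- compute_metrics(confusion_matrix(truth, pred))
  # precision: 2/4 for diploid, 0 for the unpredicted classes
  expect_equal(r$precision, mean(c(0.5, 0, 0)))
})

test_that("metrics_table assembles model x phase rows", {
  truth <- rep(ploidy_classes(), 5)
  r <- compute_metrics(confusion_matrix(truth, truth))
  tab <- metrics_table(list(pnn_train = r, pnn_test = r))
  expect_equal(tab$model, c("pnn", "pnn"))
  expect_equal(tab$phase, c("train", "test"))
  expect_equal(tab$accuracy, c(100, 100))
})
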