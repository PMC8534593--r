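test_that("sensitivity, precision, accuracy and specificity are the defining ratios", {
  expect_equal(asPercent(sensitivity(binaryCounts(116, 0, 0, 15))), 88.5)
  expect_equal(asPercent(sensitivity(binaryCounts(48, 0, 0, 15))), 76.2)
  c1 <- binaryCounts(TP = 30, FP = 10, TN = 50, FN = 10)
  expect_equal(sensitivity(c1), 0.75)
  expect_equal(precision(c1), 0.75)
  expect_equal(accuracy(c1), 0.8)
  expect_equal(specificity(c1), 50 / 60)
  expect_equal(accuracy(binaryCounts(5, 0, 5, 0)), 1)
  expect_error(sensitivity(binaryCounts(0, 3, 4, 0)), "undefined")
  expect_error(precision(binaryCounts(0, 0, 4, 3)), "undefined")
  expect_error(binaryCounts(-1, 0, 0, 1), "non-negative")
})

test_that("one-vs-rest counts reduce multi-class matrices exactly", {
  d <- diag(c(5L, 7L, 9L))
  dimnames(d) <- list(true = 0:2, predicted = 0:2)
  for (k in c("0", "1", "2")) {
    c_ <- oneVsRestCounts(d, k)
    expect_equal(c_[["FP"]], 0L)
    expect_equal(c_[["FN"]], 0L)
  }
  # random matrices vs brute-force sample tally
  withr::with_seed(1, for (rep in 1:20) {
    y <- sample(0:2, 60, TRUE)
    p <- sample(0:2, 60, TRUE)
    cm <- confusionCounts(y, p, levels = c("0", "1", "2"))
    for (k in 0:2) {
      got <- oneVsRestCounts(cm, as.character(k))
      want <- tallyCounts(y, p, k)
      expect_identical(unclass(got), unclass(want))
      expect_equal(sum(unclass(got)), 60L)
    }
  })
})

test_that("class permutation permutes one-vs-rest counts consistently", {
  cm <- matrix(c(20L, 3L, 1L, 4L, 15L, 2L, 0L, 5L, 12L), 3, 3, byrow = TRUE,
               dimnames = list(true = c("a", "b", "c"),
                               predicted = c("a", "b", "c")))
  perm <- c(3L, 1L, 2L)
  cmp <- cm[perm, perm]
  for (k in c("a", "b", "c"))
    expect_identical(unclass(oneVsRestCounts(cm, k)),
                     unclass(oneVsRestCounts(cmp, k)))
})

test_that("the benign test row of a published-style matrix gives FN 22", {
  cm <- matrix(0L, 3, 3, dimnames = list(true = 0:2, predicted = 0:2))
  cm["1", ] <- c(10L, 111L, 12L)
  expect_equal(sum(cm["1", ]), 133L)
  expect_equal(oneVsRestCounts(cm, "1")[["FN"]], 22L)
})

test_that("ROC endpoints, trivial cases and the hand-worked case are exact", {
  r <- rocCurve(c(0, 1, 0, 1, 1), c(0, 1, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(rocCurve(rep(0.3, 10), rep(0:1, 5))$auc, 0.5)
  r6 <- rocCurve(c(.9, .8, .7, .6, .4, .2), c(1, 1, 0, 1, 0, 0))
  expect_equal(r6$auc, mannWhitneyAuc(c(.9, .8, .7, .6, .4, .2), c(1, 1, 0, 1, 0, 0)))
  expect_equal(r6$auc, 8 / 9)
  expect_equal(r6$fpr[1], 0); expect_equal(r6$tpr[1], 0)
  expect_equal(r6$fpr[length(r6$fpr)], 1)
  expect_equal(r6$tpr[length(r6$tpr)], 1)
  expect_true(all(diff(r6$fpr) >= 0) && all(diff(r6$tpr) >= 0))
  expect_error(rocCurve(1:3, c(1, 1, 1)), "both classes")
})

test_that("trapezoid AUC equals the Mann-Whitney statistic on random scores", {
  withr::with_seed(2, for (rep in 1:50) {
    n <- sample(6:40, 1)
    truth <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
    expect_equal(rocCurve(scores, truth)$auc, mannWhitneyAuc(scores, truth),
                 tolerance = 1e-12)
  })
})

test_that("our AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(3, {
    truth <- c(0, 1, sample(0:1, 38, TRUE))
    scores <- rnorm(40) + truth
    expect_equal(rocCurve(scores, truth)$auc,
                 as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE))),
                 tolerance = 1e-12)
  })
})

test_that("per-image AUC treats mask pixels as ROC samples", {
  gt <- encodeMask(diskMask(c(32, 32), c(16, 16), 6) == 255L,
                   diskMask(c(32, 32), c(16, 16), 6) == 0L)
  prob <- decodeMask(gt)$tumor * 1
  expect_equal(perImageAuc(prob, gt), 1)
  expect_equal(perImageAuc(matrix(0.4, 32, 32), gt), 0.5)
  expect_error(perImageAuc(matrix(0.5, 4, 4), matrix(0L, 4, 4)), "single-class")
})

test_that("the AUC summary counts strictly-above-cutoff images", {
  expect_equal(aucSummary(c(0.9, 0.7, 0.5, 0.3), cutoff = 0.6), 0.5)
  expect_equal(aucSummary(c(0.6, 0.61), cutoff = 0.6), 0.5)  # strict
  expect_message(s <- aucSummary(c(0.9, NA, 0.3)), "excluded")
  expect_equal(s, 0.5)
})
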