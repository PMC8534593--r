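sepClouds <- function(n = 15, d = 4, gap = 6, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n * d, 0), n),
               matrix(rnorm(n * d, gap), n),
               matrix(rnorm(n * d, 2 * gap), n))
    list(x = x, y = rep(0:2, each = n))
  })
}

test_that("all four classifier kinds separate well-separated clouds", {
  dat <- sepClouds()
  for (kind in c("dt", "knn", "svm", "nb")) {
    fc <- trainClassifier(classifierSpec(kind), dat$x, dat$y)
    cm <- evaluateClassifier(fc, dat$x, dat$y)
    expect_equal(accuracyFromConfusion(cm), 1,
                 info = paste("kind:", kind))
    expect_equal(sum(cm), length(dat$y))
    p <- predictScores(fc, dat$x)
    expect_equal(dim(p), c(length(dat$y), 3L))
    expect_equal(rowSums(p), rep(1, length(dat$y)), tolerance = 1e-6)
  }
})

test_that("1-nearest-neighbour memorizes its training labels", {
  dat <- withr::with_seed(2, list(x = matrix(rnorm(120), 30), y = rep(0:2, 10)))
  fc <- trainClassifier(classifierSpec("knn", k = 1), dat$x, dat$y)
  expect_equal(as.character(predictLabels(fc, dat$x)), as.character(dat$y))
})

test_that("naive Bayes matches the closed-form Gaussian Bayes rule on a grid", {
  dat <- withr::with_seed(3, {
    x <- rbind(cbind(rnorm(40, 0, 1), rnorm(40, 0, 2)),
               cbind(rnorm(40, 3, 1.5), rnorm(40, 4, 1)))
    list(x = x, y = rep(0:1, each = 40))
  })
  fc <- trainClassifier(classifierSpec("nb"), dat$x, dat$y)
  # analytic rule with the same plug-in estimates (sample mean, n-1 sd)
  mu <- lapply(0:1, function(k) colMeans(dat$x[dat$y == k, ]))
  sd_ <- lapply(0:1, function(k) apply(dat$x[dat$y == k, ], 2, sd))
  grid <- as.matrix(expand.grid(f1 = seq(-3, 6, by = 0.5),
                                f2 = seq(-4, 7, by = 0.5)))
  loglik <- vapply(1:2, function(k)
    rowSums(dnorm(grid, rep(mu[[k]], each = nrow(grid)),
                  rep(sd_[[k]], each = nrow(grid)), log = TRUE)),
    numeric(nrow(grid)))
  margin <- loglik[, 2] - loglik[, 1]  # equal priors
  keep <- abs(margin) > 1e-6
  oracle <- ifelse(margin > 0, "1", "0")
  pred <- as.character(predictLabels(fc, grid))
  expect_identical(pred[keep], oracle[keep])
})

test_that("confusion matrices equal brute-force tallies and resist reordering", {
  dat <- sepClouds(n = 12, gap = 2, seed = 4)  # overlapping: imperfect model
  fc <- trainClassifier(classifierSpec("dt"), dat$x, dat$y)
  pred <- predictLabels(fc, dat$x)
  cm <- evaluateClassifier(fc, dat$x, dat$y)
  # tally loop oracle
  for (i in 0:2) for (j in 0:2)
    expect_equal(cm[as.character(i), as.character(j)],
                 sum(dat$y == i & pred == as.character(j)))
  expect_equal(accuracyFromConfusion(cm), mean(as.character(dat$y) == pred))
  perm <- withr::with_seed(5, sample(length(dat$y)))
  cm_perm <- evaluateClassifier(fc, dat$x[perm, ], dat$y[perm])
  expect_identical(cm, cm_perm)
})

test_that("a perfect predictor yields a diagonal confusion matrix", {
  y <- rep(0:2, each = 4)
  cm <- confusionCounts(y, y, levels = c("0", "1", "2"))
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] == 0))
  expect_equal(unname(diag(cm)), rep(4L, 3))
})

test_that("degenerate training inputs are rejected", {
  expect_error(trainClassifier(classifierSpec("dt"), matrix(1:10, 5), rep(0, 5)),
               "at least 2 classes")
  expect_error(trainClassifier(classifierSpec("svm"),
                               matrix(c(1, NA, 3, 4), 2), c(0, 1)),
               "non-finite")
  expect_error(classifierSpec("knn", k = 0), "k must be")
})
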