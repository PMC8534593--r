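# CNN tests run at 32x32 with few iterations: the architectures are
# resolution-agnostic and the contracts under test (probability simplex,
# determinism, learning on separable data) do not depend on the full
# 256x256 working resolution used by the pipelines.

test_that("layer lists count 16/11 named layers with exactly 3 convolutions", {
  cls <- netConfig("classify", image_size = 32)
  seg <- netConfig("segment", image_size = 32)
  expect_length(layerNames(cls), 16L)
  expect_length(layerNames(seg), 11L)
  expect_equal(sum(grepl("^conv", layerNames(cls))), 3L)
  expect_equal(sum(grepl("^conv", layerNames(seg))), 3L)
  expect_error(netConfig("classify", image_size = 30), "multiple")
})

test_that("untrained classifier emits a probability simplex for any input", {
  net <- buildClassifierNet(netConfig("classify", image_size = 32, seed = 5))
  imgs <- withr::with_seed(1, replicate(4, matrix(runif(1024, 0, 255), 32, 32),
                                        simplify = FALSE))
  p <- predictClasses(net, imgs)
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-9)
  # contrast change moves the scores: no degenerate constant output
  p_hi <- predictClasses(net, list(pmin(imgs[[1]] * 2, 255)))
  expect_gt(max(abs(p_hi - p[1, ])), 1e-8)
})

test_that("identical seeds give identical weights, traces and first-step loss", {
  cfg <- netConfig("classify", image_size = 32, iterations = 3,
                   batch_size = 64, val_fraction = 0, seed = 7)
  n1 <- buildClassifierNet(cfg)
  n2 <- buildClassifierNet(cfg)
  expect_identical(n1@params, n2@params)
  dat <- tinyPhantoms(3, seed0 = 2)
  t1 <- trainClassifierNet(n1, dat$images, dat$labels)
  t2 <- trainClassifierNet(n2, dat$images, dat$labels)
  expect_identical(trainTrace(t1), trainTrace(t2))
  expect_identical(t1@params, t2@params)
})

test_that("zero learning rate freezes the full-batch loss trace", {
  cfg <- netConfig("classify", image_size = 32, iterations = 5,
                   batch_size = 64, lr = 0, val_fraction = 0, seed = 3)
  dat <- tinyPhantoms(3, seed0 = 4)
  net <- trainClassifierNet(buildClassifierNet(cfg), dat$images, dat$labels)
  tr <- trainTrace(net)
  expect_equal(nrow(tr), 5L)
  expect_true(all(abs(tr$loss - tr$loss[1]) < 1e-12))
  expect_true(all(tr$accuracy >= 0 & tr$accuracy <= 1))
})

test_that("the classifier learns strongly separated phantom classes", {
  dat <- tinyPhantoms(6, seed0 = 6)
  cfg <- netConfig("classify", image_size = 32, iterations = 120,
                   batch_size = 9, val_fraction = 0, seed = 1)
  net <- trainClassifierNet(buildClassifierNet(cfg), dat$images, dat$labels)
  p <- predictClasses(net, dat$images)
  expect_gte(mean(max.col(p) - 1L == dat$labels), 0.95)
  expect_error(trainClassifierNet(buildClassifierNet(cfg),
                                  dat$images[dat$labels != 2],
                                  dat$labels[dat$labels != 2]),
               "missing")
})

test_that("final accuracy is seed-averaged non-decreasing in class separation", {
  acc_at <- function(lesion_mean) {
    mean(vapply(1:3, function(s) {
      dat <- tinyPhantoms(4, seed0 = 10 + s,
                          lesion_means = c(benign = lesion_mean, malignant = 20))
      keep <- dat$labels != 2  # binary normal-vs-benign subproblem
      cfg <- netConfig("classify", image_size = 32, n_classes = 2,
                       iterations = 60, batch_size = 8, val_fraction = 0,
                       seed = s)
      net <- trainClassifierNet(buildClassifierNet(cfg),
                                dat$images[keep], dat$labels[keep])
      p <- predictClasses(net, dat$images[keep])
      mean(max.col(p) - 1L == dat$labels[keep])
    }, numeric(1)))
  }
  expect_gte(acc_at(60), acc_at(160) - 0.05)  # darker lesion = easier
})

test_that("untrained segmenter probabilities live in [0, 1]", {
  net <- buildSegmenterNet(netConfig("segment", image_size = 32, seed = 2))
  net@fitted <- TRUE  # probe the forward pass only
  img <- withr::with_seed(3, matrix(runif(1024, 0, 255), 32, 32))
  pm <- predictMask(net, img)
  expect_true(all(pm$prob >= 0 & pm$prob <= 1))
  expect_identical(dim(pm$prob), c(32L, 32L))
})

test_that("the segmenter learns lesion darkness on small phantoms", {
  phs <- lapply(1:8, function(i)
    generatePhantom(phantomParams("benign", image_size = c(32, 32),
                                  lesion_axes = c(7, 5), lesion_mean = 40,
                                  background_mean = 180, seed = 300 + i)))
  imgs <- lapply(phs, `[[`, "image")
  masks <- lapply(phs, `[[`, "mask")
  cfg <- netConfig("segment", image_size = 32, iterations = 80,
                   batch_size = 2, lr = 2e-3, val_fraction = 0, seed = 1)
  net <- trainSegmenterNet(buildSegmenterNet(cfg), imgs, masks)
  pm <- predictMask(net, imgs[[1]])
  tum <- decodeMask(masks[[1]])$tumor
  expect_gt(mean(pm$prob[tum]), mean(pm$prob[!tum]))
  expect_gt(perImageAuc(pm$prob, masks[[1]]), 0.9)
})

test_that("all-background targets collapse tumor probability toward zero", {
  imgs <- withr::with_seed(4, replicate(4, matrix(runif(1024, 0, 255), 32, 32),
                                        simplify = FALSE))
  masks <- replicate(4, encodeMask(matrix(FALSE, 32, 32), matrix(TRUE, 32, 32)),
                     simplify = FALSE)
  cfg <- netConfig("segment", image_size = 32, iterations = 60,
                   batch_size = 4, lr = 5e-3, val_fraction = 0, seed = 1)
  net <- trainSegmenterNet(buildSegmenterNet(cfg), imgs, masks)
  pm <- predictMask(net, imgs[[1]])
  expect_lt(mean(pm$prob), 0.05)
})

test_that("mask thresholding is the elementwise comparison it claims to be", {
  phs <- lapply(1:4, function(i)
    generatePhantom(phantomParams("benign", image_size = c(32, 32),
                                  lesion_axes = c(7, 5), lesion_mean = 40,
                                  background_mean = 180, seed = 400 + i)))
  cfg <- netConfig("segment", image_size = 32, iterations = 20,
                   batch_size = 2, val_fraction = 0, seed = 1)
  net <- trainSegmenterNet(buildSegmenterNet(cfg),
                           lapply(phs, `[[`, "image"),
                           lapply(phs, `[[`, "mask"))
  img <- phs[[1]]$image
  pm0 <- predictMask(net, img, threshold = 0)
  expect_true(all(pm0$mask == 255L))
  pm1 <- predictMask(net, img, threshold = 1 + 1e-9)
  expect_true(all(pm1$mask == 0L))
  pm <- predictMask(net, img, threshold = 0.5)
  expect_identical(pm$mask == 255L, pm$prob >= 0.5)
  expect_error(predictMask(buildSegmenterNet(netConfig("segment", image_size = 32)),
                           img), "trained")
})
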