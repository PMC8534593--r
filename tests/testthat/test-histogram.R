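test_that("histograms are normalized exact pixel tallies", {
  expect_equal(unname(computeHistogram(matrix(7L, 4, 4))[8]), 1)
  cb <- matrix(c(0L, 255L), 8, 8)
  h <- computeHistogram(cb)
  expect_equal(unname(h[c(1, 256)]), c(0.5, 0.5))
  ph <- generatePhantom(phantomParams("benign", image_size = c(64, 64),
                                      lesion_axes = c(10, 8), seed = 2))
  h <- computeHistogram(ph$image)
  expect_equal(sum(h), 1, tolerance = 1e-12)
  # brute-force per-bin tally oracle
  for (b in c(0L, 60L, 150L, 255L))
    expect_equal(unname(h[b + 1]), mean(ph$image == b))
  expect_error(computeHistogram(ph$image, region = ph$mask == 9999L), "empty")
})

test_that("four-Gaussian fit recovers well-separated generating means", {
  g <- cbind(rep(1, 4), c(30, 90, 150, 210), rep(6, 4))
  img <- generateMixtureImage(g, 65536, seed = 8)
  m <- fitFourGaussians(computeHistogram(img), seed = 1)
  expect_true(hasConverged(m))
  expect_true(all(abs(histComponents(m)[, "mean"] - g[, 2]) < 1))
  # determinism and sort canonicalization
  m2 <- fitFourGaussians(computeHistogram(img), seed = 1)
  expect_identical(histComponents(m), histComponents(m2))
  expect_false(is.unsorted(histComponents(m)[, "mean"]))
})

test_that("fitted residual beats a coarse grid-search oracle on a uniform histogram", {
  h <- rep(1 / 256, 256)
  m <- fitFourGaussians(h, seed = 1)
  bins <- 0:255
  centers <- c(32, 96, 160, 224)
  sig_grid <- c(10, 40, 80, 160)
  amp_grid <- max(h) * c(0.25, 0.75, 1, 1.25)
  curves <- lapply(1:4, function(j) {
    cs <- expand.grid(s = sig_grid, a = amp_grid)
    lapply(seq_len(nrow(cs)), function(k)
      cs$a[k] * exp(-(bins - centers[j])^2 / (2 * cs$s[k]^2)))
  })
  best <- Inf
  for (i1 in seq_along(curves[[1]])) for (i2 in seq_along(curves[[2]]))
    for (i3 in seq_along(curves[[3]])) for (i4 in seq_along(curves[[4]])) {
      r <- sum((h - curves[[1]][[i1]] - curves[[2]][[i2]] -
                  curves[[3]][[i3]] - curves[[4]][[i4]])^2)
      if (r < best) best <- r
    }
  expect_lte(histResidual(m), best + 1e-12)
})

test_that("scaling histogram counts scales amplitudes and nothing else", {
  g <- cbind(c(0.01, 0.02, 0.015, 0.01), c(40, 100, 160, 220), c(8, 10, 9, 8))
  h <- rowSums(vapply(1:4, function(j)
    g[j, 1] * exp(-((0:255) - g[j, 2])^2 / (2 * g[j, 3]^2)), numeric(256)))
  m1 <- fitFourGaussians(h, seed = 2)
  m5 <- fitFourGaussians(5 * h, seed = 2)
  c1 <- histComponents(m1); c5 <- histComponents(m5)
  expect_equal(c5[, "amplitude"], 5 * c1[, "amplitude"], tolerance = 1e-3)
  expect_equal(c5[, "mean"], c1[, "mean"], tolerance = 1e-3)
  expect_equal(c5[, "sigma"], c1[, "sigma"], tolerance = 1e-3)
})

test_that("a histogram synthesized exactly from 4 Gaussians fits to ~zero residual", {
  g <- cbind(c(0.02, 0.03, 0.025, 0.02), c(35, 95, 155, 215), c(7, 9, 8, 7))
  h <- rowSums(vapply(1:4, function(j)
    g[j, 1] * exp(-((0:255) - g[j, 2])^2 / (2 * g[j, 3]^2)), numeric(256)))
  m <- fitFourGaussians(h, seed = 1)
  expect_lt(histResidual(m), 1e-10)
  expect_equal(unname(histComponents(m)[, "mean"]), g[, 2], tolerance = 1e-3)
})

test_that("feature extraction projects the model deterministically", {
  g <- cbind(rep(1, 4), c(30, 90, 150, 210), rep(6, 4))
  img <- generateMixtureImage(g, 16384, seed = 9)
  h <- computeHistogram(img)
  m <- fitFourGaussians(h, seed = 1)
  f <- extractFeatures(m)
  expect_length(f, 4L)
  expect_identical(f, unname(histComponents(m)[, "mean"]))
  # identical histograms give identical features
  expect_identical(extractFeatures(fitFourGaussians(h, seed = 1)), f)
  # the full 12 parameters stay accessible
  all12 <- extractFeatures(m, scheme = "custom", select = 1:12)
  expect_length(all12, 12L)
  expect_identical(all12[5:8], f)
  expect_error(extractFeatures(m, scheme = "custom"), "select")
})

test_that("benign phantoms shift the low-intensity component versus normals", {
  d <- withr::local_tempdir()
  man <- generateDataset(6, seed = 21, out_dir = d, image_size = c(128, 128))
  ft <- featureTable(man, d, seed = 1)
  f1_normal <- ft$f1[ft$class == 0]
  f1_benign <- ft$f1[ft$class == 1]
  w <- stats::wilcox.test(f1_benign, f1_normal, exact = FALSE)
  expect_lt(w$p.value, 0.05)
  expect_lt(mean(f1_benign), mean(f1_normal))
})
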