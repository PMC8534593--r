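test_that("normal phantoms carry no tumor pixels and lesion classes do", {
  ph_n <- generatePhantom(phantomParams("normal", seed = 1))
  expect_false(any(ph_n$mask == 255L))
  ph_b <- generatePhantom(phantomParams("benign", seed = 1))
  ph_m <- generatePhantom(phantomParams("malignant", seed = 1))
  expect_gt(sum(ph_b$mask == 255L), 0)
  expect_gt(sum(ph_m$mask == 255L), 0)
})

test_that("smooth benign lesion area matches the rasterized-ellipse oracle", {
  p <- phantomParams("benign", lesion_axes = c(20, 12),
                     boundary_irregularity = 0, seed = 4)
  ph <- generatePhantom(p)
  n_tumor <- sum(ph$mask == 255L)
  oracle <- ellipsePixelCount(p$image_size, p$lesion_center, p$lesion_axes)
  expect_identical(n_tumor, oracle)
  expect_lt(abs(n_tumor - pi * 20 * 12) / (pi * 20 * 12), 0.05)
})

test_that("phantom generation is bit-identical for identical params", {
  p <- phantomParams("malignant", seed = 99)
  expect_identical(generatePhantom(p), generatePhantom(p))
  p2 <- phantomParams("malignant", seed = 100)
  expect_false(identical(generatePhantom(p)$image, generatePhantom(p2)$image))
})

test_that("tumor mask pixels coincide with the darkened lesion support", {
  p <- phantomParams("benign", lesion_axes = c(15, 10),
                     boundary_irregularity = 0, seed = 6)
  ph <- generatePhantom(p)
  support <- matrix(FALSE, p$image_size[1], p$image_size[2])
  for (r in seq_len(p$image_size[1]))
    for (c in seq_len(p$image_size[2]))
      support[r, c] <- ((r - p$lesion_center[1]) / 15)^2 +
        ((c - p$lesion_center[2]) / 10)^2 <= 1
  expect_identical(decodeMask(ph$mask)$tumor, support)
})

test_that("out-of-bounds lesions and bad parameters are rejected", {
  expect_error(phantomParams("benign", lesion_center = c(5, 5),
                             lesion_axes = c(30, 20)), "fit")
  expect_error(phantomParams("benign", lesion_mean = 200,
                             background_mean = 150), "hypoechoic")
  expect_error(phantomParams("benign", speckle_scale = 0), "speckle")
})

test_that("dataset generation writes a complete, reproducible manifest", {
  d1 <- withr::local_tempdir()
  man <- generateDataset(3, seed = 7, out_dir = d1, image_size = c(64, 64))
  expect_equal(nrow(man), 9L)
  expect_equal(as.vector(table(man$class)), rep(3L, 3))
  expect_true(all(file.exists(file.path(d1, man$file))))
  expect_true(all(file.exists(file.path(d1, man$mask_file))))
  expect_true(all(is.na(man$lesion_row[man$class == 0])))
  expect_true(all(man$lesion_area_px[man$class != 0] > 0))
  d2 <- withr::local_tempdir()
  man2 <- generateDataset(3, seed = 7, out_dir = d2, image_size = c(64, 64))
  expect_identical(man, man2)
  expect_error(generateDataset(0, seed = 1, out_dir = d1), "n_per_class")
})

test_that("mixture images realize their generating component", {
  g <- cbind(c(0, 1, 0, 0), c(20, 100, 180, 240), c(4, 5, 4, 4))
  img <- generateMixtureImage(g, 65536, seed = 3)
  expect_lt(abs(mean(img) - 100), 1)
  # degenerate width: all pixels collapse to the quantized mean
  g0 <- cbind(c(0, 1, 0, 0), c(100, 137, 180, 240), c(4, 0, 4, 4))
  expect_identical(unique(as.vector(generateMixtureImage(g0, 1024, seed = 1))), 137L)
  expect_error(generateMixtureImage(cbind(c(-1, 1, 1, 1), g[, 2], g[, 3]), 10, 1),
               "non-negative")
  expect_error(generateMixtureImage(cbind(rep(0, 4), g[, 2], g[, 3]), 10, 1),
               "positive")
})

test_that("equal-weight well-separated mixtures show four histogram modes", {
  g <- cbind(rep(1, 4), c(30, 90, 150, 210), rep(6, 4))
  img <- generateMixtureImage(g, 65536, seed = 5)
  h <- computeHistogram(img)
  # brute-force local-maximum scan on a smoothed histogram
  sm <- stats::filter(h, rep(1 / 9, 9), sides = 2)
  sm[is.na(sm)] <- 0
  modes <- sum(vapply(2:255, function(i)
    sm[i] > sm[i - 1] && sm[i] >= sm[i + 1] && sm[i] > max(sm) / 10, logical(1)))
  expect_equal(modes, 4L)
})

test_that("lesion/background Fisher separation grows with the intensity gap", {
  seps <- vapply(c(120, 90, 50), function(lm) {
    ph <- generatePhantom(phantomParams("benign", background_mean = 150,
                                        lesion_mean = lm, seed = 11))
    fisherSeparation(ph$image, ph$mask)
  }, numeric(1))
  expect_true(all(diff(seps) > 0))
})
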