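# Shared fixture builders: everything is generated in code at test time.

label_components8 <- busecho:::label_components8

# brute-force point-in-ellipse rasterization (independent of lesionSupport)
ellipsePixelCount <- function(size, center, axes) {
  n <- 0L
  for (r in seq_len(size[1]))
    for (c in seq_len(size[2]))
      if (((r - center[1]) / axes[1])^2 + ((c - center[2]) / axes[2])^2 <= 1)
        n <- n + 1L
  n
}

# filled-disk binary mask (255/0)
diskMask <- function(size, center, radius) {
  m <- matrix(0L, size[1], size[2])
  for (r in seq_len(size[1]))
    for (c in seq_len(size[2]))
      if ((r - center[1])^2 + (c - center[2])^2 <= radius^2) m[r, c] <- 255L
  m
}

# small high-contrast phantom set for CNN tests
tinyPhantoms <- function(n_per_class, size = 32L, seed0 = 1L,
                         lesion_means = c(benign = 70, malignant = 20)) {
  imgs <- list(); labs <- integer(0)
  k <- 0L
  for (cls in c("normal", "benign", "malignant")) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      p <- phantomParams(cls, image_size = c(size, size),
                         lesion_axes = c(size / 4, size / 5.3),
                         lesion_mean = if (cls == "malignant")
                           lesion_means[["malignant"]] else lesion_means[["benign"]],
                         background_mean = 180,
                         boundary_irregularity = if (cls == "malignant") 0.2 else 0,
                         seed = seed0 * 1000L + k)
      imgs[[k]] <- generatePhantom(p)$image
      labs[k] <- switch(cls, normal = 0L, benign = 1L, malignant = 2L)
    }
  }
  list(images = imgs, labels = labs)
}

# Mann-Whitney pair-count AUC oracle (ties counted 1/2)
mannWhitneyAuc <- function(scores, truth) {
  truth <- as.logical(truth)
  sp <- scores[truth]; sn <- scores[!truth]
  tot <- 0
  for (p in sp) tot <- tot + sum(p > sn) + 0.5 * sum(p == sn)
  tot / (length(sp) * length(sn))
}

# brute-force one-vs-rest counts by sample tally
tallyCounts <- function(truth, pred, positive) {
  binaryCounts(TP = sum(truth == positive & pred == positive),
               FP = sum(truth != positive & pred == positive),
               TN = sum(truth != positive & pred != positive),
               FN = sum(truth == positive & pred != positive))
}
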