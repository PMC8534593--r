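# Histogram feature extractor: model the 256-bin intensity histogram of an
# image as a sum of four Gaussian functions and emit a fixed-length feature
# vector per image. The fit is seeded multi-start bounded nonlinear least
# squares; starts sit at the quartile positions of the histogram mass.

#' Normalized 256-bin intensity histogram
#'
#' Bin b (b = 0..255) holds the fraction of pixels with intensity b, so the
#' histogram sums to one.
#'
#' @param img Integer matrix with values in \[0, 255\].
#' @param region Optional logical matrix restricting the tally.
#' @return Numeric vector of length 256 named "0".."255".
#' @examples
#' computeHistogram(matrix(7L, 4, 4))[8]  # all mass at bin 7
#' @export
computeHistogram <- function(img, region = NULL) {
  stopifnot(is.matrix(img))
  pix <- if (is.null(region)) as.vector(img) else img[region]
  if (length(pix) == 0L) stop("empty image region")
  if (any(pix < 0 | pix > 255)) stop("intensities must be in [0, 255]")
  counts <- tabulate(as.integer(pix) + 1L, nbins = 256L)
  h <- counts / length(pix)
  names(h) <- as.character(0:255)
  h
}

# Sum of four Gaussians over the bin grid for a parameter vector
# c(a1..a4, m1..m4, s1..s4).
fourGaussianSum <- function(p, bins = 0:255) {
  y <- rep(0, length(bins))
  for (j in 1:4)
    y <- y + p[j] * exp(-(bins - p[4 + j])^2 / (2 * p[8 + j]^2))
  y
}

fourGaussianResidual <- function(p, hist, bins = 0:255) {
  sum((hist - fourGaussianSum(p, bins))^2)
}

# weighted quantile over the bin grid
massQuantile <- function(hist, probs) {
  cw <- cumsum(hist) / sum(hist)
  vapply(probs, function(p) (0:255)[which(cw >= p)[1]], numeric(1))
}

#' Fit a four-Gaussian model to an intensity histogram
#'
#' Least-squares fit of \eqn{\sum_{j=1}^4 a_j \exp(-(b - m_j)^2 / (2 s_j^2))}
#' to the 256 histogram bins, with bound constraints (\eqn{a_j \ge 0},
#' \eqn{m_j \in [0, 255]}, \eqn{s_j \in [0.5, 255]}) via
#' [minpack.lm::nlsLM()]. Multi-start: the first start places the means at
#' the quartile positions of the histogram mass; subsequent starts are
#' seeded jitters of it. The best residual wins; components are returned
#' sorted by ascending mean. If no start converges, the best objective seen
#' (over all start and end points) is returned flagged `converged = FALSE`.
#'
#' @param hist Length-256 histogram (need not be normalized: scaling the
#'   counts by c scales the fitted amplitudes by c and leaves means and
#'   widths unchanged).
#' @param seed Integer seed for the start jitter.
#' @param n_starts Number of optimizer starts (default 8).
#' @return A [HistogramModel-class].
#' @examples
#' img <- generateMixtureImage(cbind(1, c(30, 90, 150, 210), 6), 16384, seed = 2)
#' fitFourGaussians(computeHistogram(img), seed = 1)
#' @export
fitFourGaussians <- function(hist, seed = 1L, n_starts = 8L) {
  stopifnot(length(hist) == 256L, all(is.finite(hist)), all(hist >= 0))
  bins <- 0:255
  df <- data.frame(b = bins, y = as.numeric(hist))
  lower <- c(rep(0, 4), rep(0, 4), rep(0.5, 4))
  upper <- c(rep(Inf, 4), rep(255, 4), rep(255, 4))
  base_m <- massQuantile(hist, c(0.125, 0.375, 0.625, 0.875))
  base_s <- max(2, sqrt(sum(hist * bins^2) / sum(hist) -
                          (sum(hist * bins) / sum(hist))^2) / 4)
  base_a <- pmax(hist[pmin(base_m, 255) + 1], max(hist) / 8)
  starts <- withr::with_seed(seed, {
    lapply(seq_len(n_starts), function(k) {
      if (k == 1L) {
        list(m = base_m, s = rep(base_s, 4), a = as.numeric(base_a))
      } else {
        m <- pmin(pmax(base_m + rnorm(4, 0, 20), 0), 255)
        list(m = sort(m), s = pmax(base_s * exp(rnorm(4, 0, 0.5)), 0.5),
             a = as.numeric(base_a) * exp(rnorm(4, 0, 0.5)))
      }
    })
  })
  form <- y ~ a1 * exp(-(b - m1)^2 / (2 * s1^2)) +
    a2 * exp(-(b - m2)^2 / (2 * s2^2)) +
    a3 * exp(-(b - m3)^2 / (2 * s3^2)) +
    a4 * exp(-(b - m4)^2 / (2 * s4^2))
  best <- NULL
  best_res <- Inf
  converged <- FALSE
  for (st in starts) {
    p0 <- c(st$a, st$m, st$s)
    r0 <- fourGaussianResidual(p0, hist)
    if (r0 < best_res) { best_res <- r0; best <- p0 }
    start <- list(a1 = st$a[1], a2 = st$a[2], a3 = st$a[3], a4 = st$a[4],
                  m1 = st$m[1], m2 = st$m[2], m3 = st$m[3], m4 = st$m[4],
                  s1 = st$s[1], s2 = st$s[2], s3 = st$s[3], s4 = st$s[4])
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = df, start = start,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      p <- coef(fit)[c("a1", "a2", "a3", "a4", "m1", "m2", "m3", "m4",
                       "s1", "s2", "s3", "s4")]
      r <- fourGaussianResidual(p, hist)
      if (r < best_res) { best_res <- r; best <- as.numeric(p) }
      converged <- TRUE
    }
  }
  cmp <- cbind(amplitude = best[1:4], mean = best[5:8], sigma = best[9:12])
  cmp <- cmp[order(cmp[, "mean"]), , drop = FALSE]
  rownames(cmp) <- NULL
  new("HistogramModel", components = cmp, residual = best_res,
      converged = converged)
}

#' Extract the per-image feature vector from a histogram model
#'
#' The default scheme returns the four sorted component means -- a fixed
#' length-4 summary of the fitted distributions. The full 12 raw parameters
#' stay accessible through `scheme = "custom"` with an index subset of the
#' flattened parameter vector `c(a1..a4, m1..m4, s1..s4)`.
#'
#' @param model A fitted [HistogramModel-class].
#' @param scheme `"means"` (default) or `"custom"`.
#' @param select For `"custom"`: integer indices into the 12-vector.
#' @return Numeric feature vector.
#' @export
extractFeatures <- function(model, scheme = c("means", "custom"),
                            select = NULL) {
  stopifnot(is(model, "HistogramModel"))
  scheme <- match.arg(scheme)
  cmp <- model@components
  if (scheme == "means") return(unname(cmp[, "mean"]))
  if (is.null(select)) stop("scheme 'custom' requires select indices")
  flat <- c(cmp[, "amplitude"], cmp[, "mean"], cmp[, "sigma"])
  unname(flat[select])
}

#' Histogram features for every image in a manifest
#'
#' Fits the four-Gaussian model to each image and collects the feature
#' vectors into a table.
#'
#' @param manifest Manifest `data.frame` (columns `file`, `class`).
#' @param dir Directory containing the image files.
#' @param scheme Passed to [extractFeatures()].
#' @param seed Integer seed for the fits.
#' @return `data.frame` with columns `file`, `class`, `f1`..`f4`,
#'   `residual`, `converged`.
#' @export
featureTable <- function(manifest, dir, scheme = "means", seed = 1L) {
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- loadImage(file.path(dir, manifest$file[i]))
    model <- fitFourGaussians(computeHistogram(img), seed = seed)
    f <- extractFeatures(model, scheme = scheme)
    data.frame(file = manifest$file[i], class = manifest$class[i],
               f1 = f[1], f2 = f[2], f3 = f[3], f4 = f[4],
               residual = model@residual, converged = model@converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
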