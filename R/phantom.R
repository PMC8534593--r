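# Synthetic ultrasound-like phantoms. The generator defines the study
# conditions for all downstream tests: speckled background, a hypoechoic
# (dark) elliptical lesion -- smooth for benign, spiculated for malignant --
# and a three-level ground-truth mask (tumor 255, tissue 127, background 0).

CLASS_LEVELS <- c(normal = 0L, benign = 1L, malignant = 2L)

#' Phantom parameters
#'
#' Bundle and validate the parameters of a single synthetic phantom. The
#' lesion (absent for class `"normal"`) is a hypoechoic ellipse; malignant
#' lesions get an irregular, spiculated boundary via a smooth seeded radial
#' perturbation.
#'
#' @param class_label `"normal"`, `"benign"` or `"malignant"`.
#' @param image_size Integer vector (rows, cols); default `c(256, 256)`.
#' @param lesion_center Numeric (row, col), 1-based; default: image center.
#' @param lesion_axes Numeric (a, b): semi-axes in pixels (row, col
#'   direction).
#' @param boundary_irregularity Non-negative amplitude of the radial boundary
#'   perturbation; 0 is a smooth ellipse. Defaults: 0 (benign), 0.35
#'   (malignant).
#' @param background_mean,lesion_mean Template intensities in \[0, 255\];
#'   the lesion must be darker than the background (hypoechoic).
#' @param speckle_scale Relative standard deviation of the multiplicative
#'   speckle (> 0); the speckle is unit-mean gamma with shape
#'   `1 / speckle_scale^2`, the standard first-order approximation of
#'   fully-developed ultrasound speckle.
#' @param seed Integer seed making the phantom fully deterministic.
#' @return A list of class `"PhantomParams"`.
#' @examples
#' p <- phantomParams("benign", lesion_axes = c(20, 12), seed = 7)
#' @export
phantomParams <- function(class_label = c("benign", "malignant", "normal"),
                          image_size = c(256L, 256L),
                          lesion_center = NULL,
                          lesion_axes = c(30, 20),
                          boundary_irregularity = NULL,
                          background_mean = 150,
                          lesion_mean = 60,
                          speckle_scale = 0.25,
                          seed = 1L) {
  class_label <- match.arg(class_label)
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2L, all(image_size >= 16L))
  if (is.null(lesion_center)) lesion_center <- (image_size + 1) / 2
  if (is.null(boundary_irregularity))
    boundary_irregularity <- if (class_label == "malignant") 0.35 else 0
  if (boundary_irregularity < 0)
    stop("boundary_irregularity must be >= 0")
  if (speckle_scale <= 0) stop("speckle_scale must be > 0")
  if (background_mean < 0 || background_mean > 255 ||
      lesion_mean < 0 || lesion_mean > 255)
    stop("intensity means must be in [0, 255]")
  if (class_label != "normal") {
    if (lesion_mean >= background_mean)
      stop("lesion_mean must be below background_mean (hypoechoic lesion)")
    reach <- lesion_axes * (1 + boundary_irregularity)
    if (lesion_center[1] - reach[1] < 1 || lesion_center[1] + reach[1] > image_size[1] ||
        lesion_center[2] - reach[2] < 1 || lesion_center[2] + reach[2] > image_size[2])
      stop("lesion does not fit inside the image bounds")
  }
  structure(list(class_label = class_label, image_size = image_size,
                 lesion_center = as.numeric(lesion_center),
                 lesion_axes = as.numeric(lesion_axes),
                 boundary_irregularity = boundary_irregularity,
                 background_mean = background_mean, lesion_mean = lesion_mean,
                 speckle_scale = speckle_scale, seed = as.integer(seed)),
            class = "PhantomParams")
}

# Boolean lesion support for given params; coefficients for the malignant
# boundary must already have been drawn (passed as a function of theta).
lesionSupport <- function(params, perturb = NULL) {
  h <- params$image_size[1]; w <- params$image_size[2]
  dr <- (seq_len(h) - params$lesion_center[1]) / params$lesion_axes[1]
  dc <- (seq_len(w) - params$lesion_center[2]) / params$lesion_axes[2]
  RR <- outer(dr, rep(1, w))
  CC <- outer(rep(1, h), dc)
  rho <- sqrt(RR^2 + CC^2)
  if (is.null(perturb) || params$boundary_irregularity == 0) return(rho <= 1)
  theta <- atan2(CC, RR)
  limit <- pmax(1 + params$boundary_irregularity * perturb(theta), 0.2)
  rho <= limit
}

#' Generate one synthetic phantom
#'
#' Renders a speckled grayscale image and its ground-truth mask. The image
#' is a piecewise-smooth template (dark border outside the scan ellipse,
#' tissue at `background_mean`, lesion at `lesion_mean`), lightly blurred and
#' multiplied by unit-mean gamma speckle, then quantized to 8 bits. The mask
#' encodes tumor 255, normal tissue 127, background 0.
#'
#' Identical `params` (including the seed) give bit-identical output.
#'
#' @param params A [phantomParams()] object.
#' @return List with integer matrices `image` and `mask`, plus `params`.
#' @examples
#' ph <- generatePhantom(phantomParams("benign", lesion_axes = c(20, 12)))
#' table(ph$mask)
#' @export
generatePhantom <- function(params) {
  stopifnot(inherits(params, "PhantomParams"))
  h <- params$image_size[1]; w <- params$image_size[2]
  withr::with_seed(params$seed, {
    perturb <- if (params$class_label == "malignant" &&
                   params$boundary_irregularity > 0) {
      a <- rnorm(4L); b <- rnorm(4L)
      function(theta) {
        g <- rep(0, length(theta))
        for (k in 1:4) g <- g + a[k] * cos((k + 1) * theta) + b[k] * sin((k + 1) * theta)
        m <- max(abs(g)); if (m > 0) g / m else g
      }
    } else NULL
    # scan area: large centered ellipse; corners are echo-free background
    rr <- (seq_len(h) - (h + 1) / 2) / (0.62 * h)
    cc <- (seq_len(w) - (w + 1) / 2) / (0.62 * w)
    scan <- outer(rr^2, cc^2, `+`) <= 1
    tumor <- if (params$class_label == "normal") {
      matrix(FALSE, h, w)
    } else {
      lesionSupport(params, perturb)
    }
    template <- matrix(6, h, w)
    template[scan] <- params$background_mean
    template[tumor] <- params$lesion_mean
    template <- ebiBlur(template, sigma = 1.2)
    shape <- 1 / params$speckle_scale^2
    speckle <- matrix(rgamma(h * w, shape = shape, rate = shape), h, w)
    img <- pmin(pmax(round(template * speckle), 0), 255)
    storage.mode(img) <- "integer"
    mask <- encodeMask(tumor, scan & !tumor)
    list(image = img, mask = mask, params = params)
  })
}

# light Gaussian blur via EBImage (keeps raster orientation)
ebiBlur <- function(m, sigma) {
  t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(m)), sigma = sigma)))
}

#' Generate a labelled phantom dataset on disk
#'
#' Writes `n_per_class` phantoms per class (normal, benign, malignant) as
#' 8-bit grayscale PNGs with paired ground-truth masks, and a CSV manifest
#' recording the file names, class label and lesion truth (center, pixel
#' area). Lesion geometry and contrast are randomized within realistic
#' ranges, deterministically from `seed`.
#'
#' @param n_per_class Integer >= 1.
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if needed).
#' @param image_size Integer vector (rows, cols).
#' @param contrast Multiplier (> 0) on the background/lesion intensity gap;
#'   larger values give easier, higher-contrast lesions.
#' @return The manifest `data.frame` (invisibly also written to
#'   `manifest.csv` in `out_dir`) with columns `file`, `mask_file`, `class`,
#'   `lesion_row`, `lesion_col`, `lesion_area_px`.
#' @export
generateDataset <- function(n_per_class, seed, out_dir,
                            image_size = c(256L, 256L), contrast = 1) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  h <- image_size[1]; w <- image_size[2]
  rows <- withr::with_seed(seed, {
    recs <- list()
    for (cls in names(CLASS_LEVELS)) {
      for (i in seq_len(n_per_class)) {
        sub_seed <- sample.int(.Machine$integer.max - 1L, 1L)
        bg <- runif(1, 140, 170)
        lm <- max(5, bg - contrast * runif(1, 70, 110))
        axes <- c(runif(1, h / 14, h / 8), runif(1, w / 16, w / 9))
        irr <- switch(cls, normal = 0, benign = runif(1, 0, 0.05),
                      malignant = runif(1, 0.25, 0.45))
        reach <- ceiling(axes * (1 + irr)) + 2
        center <- c(runif(1, 1 + reach[1], h - reach[1]),
                    runif(1, 1 + reach[2], w - reach[2]))
        # keep lesion inside the scan ellipse: pull towards the center
        center <- (center + c(h + 1, w + 1) / 2) / 2
        p <- phantomParams(cls, image_size = image_size,
                           lesion_center = center, lesion_axes = axes,
                           boundary_irregularity = irr,
                           background_mean = bg, lesion_mean = lm,
                           seed = sub_seed)
        ph <- generatePhantom(p)
        file <- sprintf("img_%s_%03d.png", cls, i)
        mask_file <- sprintf("mask_%s_%03d.png", cls, i)
        saveImage(ph$image, file.path(out_dir, file))
        saveImage(ph$mask, file.path(out_dir, mask_file))
        recs[[length(recs) + 1L]] <- data.frame(
          file = file, mask_file = mask_file, class = CLASS_LEVELS[[cls]],
          lesion_row = if (cls == "normal") NA_real_ else center[1],
          lesion_col = if (cls == "normal") NA_real_ else center[2],
          lesion_area_px = sum(ph$mask == 255L))
      }
    }
    do.call(rbind, recs)
  })
  rownames(rows) <- NULL
  writeManifest(rows, file.path(out_dir, "manifest.csv"))
  rows
}

#' Generate an image realizing a known four-Gaussian histogram
#'
#' Inverse problem used to test histogram-fit recovery: draws `n_pixels`
#' i.i.d. intensities from the mixture whose component areas are
#' proportional to `amplitude * sigma`, clips to \[0, 255\] and quantizes to
#' integers, and shapes the result as a (near-)square matrix.
#'
#' @param gauss_params 4 x 3 numeric matrix (columns amplitude, mean, sigma)
#'   or a [HistogramModel-class].
#' @param n_pixels Number of pixels to draw.
#' @param seed Integer seed.
#' @return Integer matrix with `n_pixels` entries.
#' @examples
#' g <- cbind(c(1, 1, 1, 1), c(40, 100, 160, 220), c(6, 6, 6, 6))
#' img <- generateMixtureImage(g, 4096, seed = 1)
#' @export
generateMixtureImage <- function(gauss_params, n_pixels, seed) {
  if (is(gauss_params, "HistogramModel")) gauss_params <- gauss_params@components
  gp <- as.matrix(gauss_params)
  stopifnot(all(dim(gp) == c(4L, 3L)))
  if (any(gp[, 1] < 0)) stop("mixture weights must be non-negative")
  if (all(gp[, 1] <= 0)) stop("at least one mixture weight must be positive")
  if (any(gp[, 3] < 0)) stop("sigmas must be non-negative")
  if (any(gp[, 2] < 0 | gp[, 2] > 255)) stop("means must be in [0, 255]")
  w <- gp[, 1] * pmax(gp[, 3], .Machine$double.eps)  # area under each Gaussian
  w <- w / sum(w)
  vals <- withr::with_seed(seed, {
    comp <- sample.int(4L, n_pixels, replace = TRUE, prob = w)
    rnorm(n_pixels, mean = gp[comp, 2], sd = gp[comp, 3])
  })
  vals <- as.integer(pmin(pmax(round(vals), 0), 255))
  h <- floor(sqrt(n_pixels))
  while (n_pixels %% h != 0) h <- h - 1L
  matrix(vals, nrow = h)
}

#' Fisher separation of lesion vs background intensities
#'
#' Convenience diagnostic: \eqn{(\mu_1 - \mu_0)^2 / (v_1 + v_0)} between the
#' pixels inside and outside the tumor mask, used to quantify how separable
#' a phantom's lesion is.
#'
#' @param image,mask Matrices from [generatePhantom()].
#' @return A single non-negative number.
#' @export
fisherSeparation <- function(image, mask) {
  inside <- image[mask == 255L]
  outside <- image[mask == 127L]
  (mean(inside) - mean(outside))^2 / (var(inside) + var(outside))
}
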