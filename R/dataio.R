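# Image/mask I/O, the three-level mask codec, resizing, and seeded
# stratified splits. Images are integer matrices in [0, 255]; masks use the
# alphabet {0 background, 127 normal tissue, 255 tumor}. The decoder also
# accepts 225 as tumor (a value some ground-truth sources print for the
# tumor label) and normalizes it to 255 on read.

MASK_TUMOR <- 255L
MASK_TISSUE <- 127L
MASK_BACKGROUND <- 0L

#' Load / save an 8-bit grayscale image
#'
#' `loadImage` reads a PNG into an integer matrix in \[0, 255\]. RGB(A) input
#' is converted to grayscale with the standard luma weights
#' (0.299 R + 0.587 G + 0.114 B), with a message. `saveImage` writes an
#' integer matrix as an 8-bit grayscale PNG; the round trip
#' `loadImage(saveImage(x))` is exact.
#'
#' @param path File path.
#' @param img Integer (or numeric) matrix with values in \[0, 255\].
#' @return `loadImage`: an integer matrix; `saveImage`: `path`, invisibly.
#' @export
loadImage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    message("RGB input converted to grayscale by luma: ", path)
    a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  }
  m <- round(a * 255)
  storage.mode(m) <- "integer"
  m
}

#' @rdname loadImage
#' @export
saveImage <- function(img, path) {
  stopifnot(is.matrix(img))
  if (any(img < 0 | img > 255)) stop("intensities must be in [0, 255]")
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Resize an image or mask to the working resolution
#'
#' Images are resampled with bilinear interpolation; masks use
#' nearest-neighbour so the label alphabet {0, 127, 255} is preserved
#' exactly. An input already at the target size is returned unchanged.
#'
#' @param img Integer matrix (image or mask).
#' @param size Target (rows, cols); default `c(256, 256)`.
#' @param kind `"image"` (bilinear) or `"mask"` (nearest-neighbour).
#' @return Integer matrix of dimension `size`.
#' @export
standardizeImage <- function(img, size = c(256L, 256L), kind = c("image", "mask")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(img))
  if (nrow(img) == 0L || ncol(img) == 0L) stop("zero-sized input image")
  if (all(dim(img) == size)) return(img)
  filt <- if (kind == "image") "bilinear" else "none"
  out <- t(EBImage::imageData(EBImage::resize(
    EBImage::Image(t(img)), w = size[2], h = size[1], filter = filt)))
  out <- pmin(pmax(round(out), 0), 255)
  storage.mode(out) <- "integer"
  out
}

#' Encode / decode the three-level ground-truth mask
#'
#' `encodeMask` maps disjoint boolean rasters to the label alphabet: tumor
#' pixels 255, tissue pixels 127, everything else 0. `decodeMask` inverts
#' exactly, returning the three boolean rasters; the tumor label 225 is
#' accepted as a synonym of 255.
#'
#' @param tumor_region,tissue_region Logical matrices of equal dimension;
#'   they must not overlap.
#' @param mask Integer matrix over {0, 127, 225, 255}.
#' @return `encodeMask`: integer matrix; `decodeMask`: list of logical
#'   matrices `tumor`, `tissue`, `background`.
#' @examples
#' m <- encodeMask(diag(3) > 0, matrix(FALSE, 3, 3))
#' decodeMask(m)$tumor
#' @export
encodeMask <- function(tumor_region, tissue_region) {
  stopifnot(is.logical(tumor_region), is.logical(tissue_region),
            all(dim(tumor_region) == dim(tissue_region)))
  if (any(tumor_region & tissue_region))
    stop("tumor and tissue regions overlap")
  mask <- matrix(MASK_BACKGROUND, nrow(tumor_region), ncol(tumor_region))
  mask[tissue_region] <- MASK_TISSUE
  mask[tumor_region] <- MASK_TUMOR
  storage.mode(mask) <- "integer"
  mask
}

#' @rdname encodeMask
#' @export
decodeMask <- function(mask) {
  stopifnot(is.matrix(mask))
  bad <- setdiff(unique(as.vector(mask)), c(0L, 127L, 225L, 255L))
  if (length(bad))
    stop("mask contains values outside {0, 127, 255}: ",
         paste(bad, collapse = ", "))
  tumor <- mask == 255L | mask == 225L
  tissue <- mask == 127L
  list(tumor = tumor, tissue = tissue, background = !(tumor | tissue))
}

#' Read / write a dataset manifest
#'
#' The manifest is a CSV with one row per image: `file`, `mask_file`,
#' `class` (0 normal, 1 benign, 2 malignant), optional lesion truth columns
#' and, after [splitDataset()], a `split` column.
#'
#' @param path CSV path.
#' @param manifest A manifest `data.frame`.
#' @return `readManifest`: a `data.frame`; `writeManifest`: `path`, invisibly.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname readManifest
#' @export
writeManifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Seeded stratified train/test split
#'
#' Assigns each manifest row to `"train"` or `"test"`, stratified by class:
#' within every class, `round(ratio * n)` rows go to train after a seeded
#' shuffle, so the per-class train fraction deviates from `ratio` by less
#' than one item. Deterministic given the seed.
#'
#' @param manifest Manifest `data.frame` with a `class` column.
#' @param ratio Train fraction, strictly between 0 and 1; default 0.7.
#' @param seed Integer seed.
#' @return The manifest with a `split` column.
#' @examples
#' m <- data.frame(file = sprintf("i%02d.png", 1:30), class = rep(0:2, each = 10))
#' table(splitDataset(m, 0.7, seed = 1)[, c("class", "split")])
#' @export
splitDataset <- function(manifest, ratio = 0.7, seed = 1L) {
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  if (!"class" %in% names(manifest)) stop("manifest lacks a class column")
  split <- rep("test", nrow(manifest))
  withr::with_seed(seed, {
    for (cl in sort(unique(manifest$class))) {
      idx <- which(manifest$class == cl)
      if (length(idx) < 2L)
        stop("class ", cl, " has fewer than 2 items; cannot split")
      n_train <- round(ratio * length(idx))
      split[sample(idx)[seq_len(n_train)]] <- "train"
    }
  })
  manifest$split <- split
  manifest
}
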