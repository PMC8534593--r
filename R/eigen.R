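# Eigenface-style feature path: stack the images into a centered data
# matrix, then obtain the eigenpairs of the big covariance A A^T through the
# small M x M matrix A^T A (U_i = A V_i), which shares its nonzero spectrum.

#' Build the centered image data matrix
#'
#' Reshapes M same-sized images into columns of an N^2 x M matrix, computes
#' the per-pixel mean image and variance image, and centers the columns by
#' the mean image.
#'
#' @param images List of >= 2 numeric matrices, all the same dimension.
#' @return List of class `"DataMatrix"`: `A` (centered N^2 x M matrix),
#'   `meanImage`, `varianceImage` (length-N^2 vectors), `imageDim`, `M`.
#' @examples
#' imgs <- replicate(3, matrix(rnorm(16), 4, 4), simplify = FALSE)
#' d <- buildDataMatrix(imgs)
#' range(rowMeans(d$A))  # ~ 0: columns centered
#' @export
buildDataMatrix <- function(images) {
  if (length(images) < 2L) stop("need at least 2 images")
  d1 <- dim(images[[1L]])
  ok <- vapply(images, function(x) is.matrix(x) && all(dim(x) == d1), logical(1))
  if (!all(ok)) stop("all images must be matrices of the same dimension")
  X <- vapply(images, function(x) as.numeric(x), numeric(prod(d1)))
  f <- rowMeans(X)
  v <- rowMeans((X - f)^2)
  structure(list(A = X - f, meanImage = f, varianceImage = v,
                 imageDim = as.integer(d1), M = length(images)),
            class = "DataMatrix")
}

#' Eigen-decompose the image covariance via the small-matrix trick
#'
#' Computes the eigenpairs of the M x M matrix \eqn{A^T A} and maps its
#' eigenvectors \eqn{V_i} to eigenvectors of the N^2 x N^2 covariance
#' \eqn{A A^T} by \eqn{U_i = A V_i}, then normalizes. The nonzero
#' eigenvalues of the two matrices coincide, so the full covariance is never
#' formed. Eigenvector signs are fixed by making the largest-magnitude entry
#' positive.
#'
#' @param D A `"DataMatrix"` from [buildDataMatrix()].
#' @return An [EigenFeatureModel-class].
#' @export
eigenDecompose <- function(D) {
  stopifnot(inherits(D, "DataMatrix"))
  S <- crossprod(D$A)                      # M x M = A^T A
  e <- tryCatch(eigen(S, symmetric = TRUE),
                error = function(err) stop("eigendecomposition failed: ",
                                           conditionMessage(err)))
  vals <- pmax(e$values, 0)
  tol <- max(vals) * 1e-10 + 1e-12
  rank <- sum(vals > tol)
  if (rank > 0L) {
    U <- D$A %*% e$vectors[, seq_len(rank), drop = FALSE]
    nrm <- sqrt(colSums(U^2))
    U <- sweep(U, 2L, nrm, "/")
    for (j in seq_len(rank)) {
      k <- which.max(abs(U[, j]))
      if (U[k, j] < 0) U[, j] <- -U[, j]
    }
  } else {
    U <- matrix(numeric(0), nrow = prod(D$imageDim), ncol = 0L)
  }
  new("EigenFeatureModel", meanImage = D$meanImage, eigenvalues = vals,
      basis = U, rank = as.integer(rank), imageDim = D$imageDim)
}

#' Project an image onto the top-f eigenvectors
#'
#' Returns \eqn{W^T (x - \mu)} where W holds the f leading eigenvectors and
#' \eqn{\mu} is the training mean image: the scatter-maximizing f-dimensional
#' features of the image.
#'
#' @param model An [EigenFeatureModel-class].
#' @param img Numeric matrix of the training image dimension.
#' @param f Number of retained eigenvectors, `1 <= f <= rank`.
#' @return Numeric vector of length `f`.
#' @export
projectImage <- function(model, img, f) {
  stopifnot(is(model, "EigenFeatureModel"))
  if (f < 1L || f > model@rank)
    stop("f must be between 1 and the model rank (", model@rank, ")")
  x <- as.numeric(img)
  if (length(x) != length(model@meanImage)) stop("image dimension mismatch")
  drop(crossprod(model@basis[, seq_len(f), drop = FALSE], x - model@meanImage))
}

#' Reconstruct an image from its projection
#'
#' Inverse of [projectImage()] restricted to the span of the top-f
#' eigenvectors: \eqn{W z + \mu}. At `f = rank` this reproduces any training
#' image exactly (up to numerical error).
#'
#' @param model An [EigenFeatureModel-class].
#' @param scores Projection vector of length f.
#' @return Numeric matrix of the training image dimension.
#' @export
reconstructImage <- function(model, scores) {
  f <- length(scores)
  if (f < 1L || f > model@rank) stop("scores length must be in 1..rank")
  x <- model@basis[, seq_len(f), drop = FALSE] %*% scores + model@meanImage
  matrix(x, model@imageDim[1], model@imageDim[2])
}

#' Cumulative explained variance of the eigen model
#'
#' @param model An [EigenFeatureModel-class].
#' @return Non-decreasing vector reaching 1 at full rank.
#' @export
explainedVariance <- function(model) {
  v <- model@eigenvalues
  cumsum(v) / sum(v)
}
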