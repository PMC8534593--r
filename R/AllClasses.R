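# S4 containers for the fitted models and reports. Images and masks stay
# plain integer matrices (rows = image rows, 1-based coordinates): they are
# the universal currency of the package and a matrix is the idiomatic raster.

#' Four-Gaussian histogram model
#'
#' Parameters of the decomposition of a 256-bin intensity histogram into a
#' sum of four Gaussian functions \eqn{\sum_j a_j \exp(-(b - m_j)^2 / (2 s_j^2))}.
#' Components are stored sorted by ascending mean.
#'
#' @slot components 4 x 3 numeric matrix with columns `amplitude`, `mean`,
#'   `sigma`, rows sorted by ascending mean.
#' @slot residual Sum of squared differences between the histogram and the
#'   fitted mixture over the 256 bins.
#' @slot converged Logical; `FALSE` means no optimizer start converged and
#'   the best objective value seen is reported instead.
#' @seealso [fitFourGaussians()], [extractFeatures()]
#' @export
setClass("HistogramModel",
  representation(components = "matrix", residual = "numeric",
                 converged = "logical"),
  validity = function(object) {
    cmp <- object@components
    if (!all(dim(cmp) == c(4L, 3L)))
      return("components must be a 4 x 3 matrix (amplitude, mean, sigma)")
    if (is.unsorted(cmp[, 2L])) return("components must be sorted by mean")
    if (any(cmp[, 1L] < 0)) return("amplitudes must be non-negative")
    if (any(cmp[, 3L] <= 0)) return("sigmas must be positive")
    if (object@residual < 0) return("residual must be non-negative")
    TRUE
  })

#' Eigen feature model
#'
#' Mean image, eigenvalues and orthonormal eigenvectors of the image
#' covariance matrix \eqn{A A^T}, computed through the eigendecomposition of
#' the small \eqn{M \times M} matrix \eqn{A^T A} (so at most M - 1 nonzero
#' eigenvalues). Columns of `basis` are unit-norm, pairwise orthogonal, and
#' sign-fixed so the largest-magnitude entry is positive.
#'
#' @slot meanImage Numeric vector of length N^2 (the per-pixel mean).
#' @slot eigenvalues Numeric vector, descending, length M.
#' @slot basis N^2 x r matrix of eigenvectors for the r nonzero eigenvalues.
#' @slot rank Integer, number of retained (nonzero) eigenvectors.
#' @slot imageDim Integer vector (rows, cols) of the training images.
#' @seealso [eigenDecompose()], [projectImage()]
#' @export
setClass("EigenFeatureModel",
  representation(meanImage = "numeric", eigenvalues = "numeric",
                 basis = "matrix", rank = "integer", imageDim = "integer"),
  validity = function(object) {
    if (is.unsorted(rev(object@eigenvalues))) return("eigenvalues must be descending")
    if (any(object@eigenvalues < -1e-8)) return("eigenvalues must be >= -1e-8")
    if (ncol(object@basis) != object@rank) return("basis/rank mismatch")
    if (nrow(object@basis) != prod(object@imageDim)) return("basis/imageDim mismatch")
    TRUE
  })

#' Fitted classical classifier
#'
#' Wraps one of the four classical models (decision tree, k-nearest
#' neighbour, support vector machine, naive Bayes) together with the
#' training-set standardization used for the scale-sensitive kinds.
#'
#' @slot kind One of `"dt"`, `"knn"`, `"svm"`, `"nb"`.
#' @slot fit The underlying fitted model object.
#' @slot center,scale Feature standardization statistics (length 0 when the
#'   kind is scale-invariant).
#' @slot levels Class labels, always `c("0", "1", "2")` order for the
#'   three-class problem.
#' @slot spec The hyperparameter list used at training time.
#' @export
setClass("FittedClassifier",
  representation(kind = "character", fit = "ANY", center = "numeric",
                 scale = "numeric", levels = "character", spec = "list"),
  validity = function(object) {
    if (!object@kind %in% c("dt", "knn", "svm", "nb"))
      return("kind must be one of dt, knn, svm, nb")
    TRUE
  })

#' Small convolutional network
#'
#' Holds the configuration, parameters and optimizer-independent state of
#' one of the two networks: the 16-layer / 3-convolution image classifier
#' or the 11-layer / 3-convolution pixel labeller.
#'
#' @slot cfg Configuration list from [netConfig()].
#' @slot params Named list of weight arrays.
#' @slot state Named list (batch-norm running statistics).
#' @slot fitted Logical, `TRUE` after training.
#' @slot trace data.frame with per-iteration `loss`, `accuracy` and sparse
#'   `val_accuracy` checkpoints.
#' @export
setClass("EchoNet",
  representation(cfg = "list", params = "list", state = "list",
                 fitted = "logical", trace = "data.frame"),
  validity = function(object) {
    ln <- layerNames(object@cfg)
    want <- if (object@cfg$task == "classify") 16L else 11L
    if (length(ln) != want)
      return(sprintf("%s net must have %d named layers", object@cfg$task, want))
    if (sum(grepl("^conv", ln)) != 3L)
      return("net must have exactly 3 convolution layers")
    TRUE
  })

#' Lesion localization report
#'
#' Location and size of the largest connected tumor component of a refined
#' binary mask. A single 2-D frame cannot yield a physical volume, so size is
#' reported as an area (pixels, optionally mm^2 via a pixel spacing).
#'
#' @slot present Logical; `FALSE` for an empty mask (geometric slots are NA).
#' @slot centroid Numeric (row, col), 1-based pixel coordinates.
#' @slot area Numeric, pixel count of the largest component.
#' @slot areaPhysical Numeric, `area * spacing^2` in mm^2 (NA without spacing).
#' @slot bbox Numeric (row_min, row_max, col_min, col_max).
#' @slot nComponentsBefore,nComponentsAfter Component counts before/after
#'   morphological refinement (before is NA when unknown).
#' @seealso [lesionReport()], [morphologicalRefine()]
#' @export
setClass("LesionReport",
  representation(present = "logical", centroid = "numeric", area = "numeric",
                 areaPhysical = "numeric", bbox = "numeric",
                 nComponentsBefore = "numeric", nComponentsAfter = "numeric"),
  validity = function(object) {
    if (object@present) {
      if (is.na(object@area) || object@area < 1) return("present lesion needs area >= 1")
      b <- object@bbox
      cen <- object@centroid
      if (cen[1] < b[1] - 0.5 || cen[1] > b[2] + 0.5 ||
          cen[2] < b[3] - 0.5 || cen[2] > b[4] + 0.5)
        return("centroid must lie inside the bounding box")
    }
    TRUE
  })

setMethod("show", "HistogramModel", function(object) {
  cat("HistogramModel: 4-Gaussian histogram decomposition\n")
  cmp <- object@components
  for (j in 1:4)
    cat(sprintf("  component %d: amplitude %.4g  mean %.2f  sigma %.2f\n",
                j, cmp[j, 1], cmp[j, 2], cmp[j, 3]))
  cat(sprintf("  residual %.4g  converged %s\n", object@residual, object@converged))
})

setMethod("show", "EigenFeatureModel", function(object) {
  cat(sprintf("EigenFeatureModel: %d x %d images, rank %d\n",
              object@imageDim[1], object@imageDim[2], object@rank))
  ev <- object@eigenvalues[seq_len(min(5L, length(object@eigenvalues)))]
  cat("  leading eigenvalues:", paste(signif(ev, 4), collapse = ", "), "\n")
})

setMethod("show", "FittedClassifier", function(object) {
  cat(sprintf("FittedClassifier: kind '%s', classes {%s}\n",
              object@kind, paste(object@levels, collapse = ", ")))
})

setMethod("show", "EchoNet", function(object) {
  cat(sprintf("EchoNet (%s): %d named layers, 3 convolutions, %s\n",
              object@cfg$task, length(layerNames(object@cfg)),
              if (object@fitted) "fitted" else "untrained"))
  cat(sprintf("  input %dx%dx1, %d parameters\n", object@cfg$image_size,
              object@cfg$image_size, parameterCount(object)))
})

setMethod("show", "LesionReport", function(object) {
  if (!object@present) {
    cat("LesionReport: no lesion present\n")
  } else {
    cat(sprintf("LesionReport: centroid (%.1f, %.1f), area %d px",
                object@centroid[1], object@centroid[2], as.integer(object@area)))
    if (!is.na(object@areaPhysical))
      cat(sprintf(" (%.2f mm^2)", object@areaPhysical))
    cat("\n")
  }
})

# -- accessors ---------------------------------------------------------------

#' Accessors for fitted model objects
#'
#' @param object A [HistogramModel-class], [EigenFeatureModel-class] or
#'   [LesionReport-class].
#' @return `histComponents`: the 4 x 3 component matrix; `histResidual` /
#'   `hasConverged`: fit diagnostics; `eigenValues` / `eigenBasis` /
#'   `meanImage`: slots of the eigen model; `lesionCentroid` / `lesionArea` /
#'   `lesionPresent`: slots of a lesion report.
#' @name accessors
NULL

#' @rdname accessors
#' @export
histComponents <- function(object) object@components
#' @rdname accessors
#' @export
histResidual <- function(object) object@residual
#' @rdname accessors
#' @export
hasConverged <- function(object) object@converged
#' @rdname accessors
#' @export
eigenValues <- function(object) object@eigenvalues
#' @rdname accessors
#' @export
eigenBasis <- function(object) object@basis
#' @rdname accessors
#' @export
meanImage <- function(object) matrix(object@meanImage, object@imageDim[1], object@imageDim[2])
#' @rdname accessors
#' @export
lesionPresent <- function(object) object@present
#' @rdname accessors
#' @export
lesionCentroid <- function(object) object@centroid
#' @rdname accessors
#' @export
lesionArea <- function(object) object@area
#' @rdname accessors
#' @export
trainTrace <- function(object) object@trace
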