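# Classical classification stage: decision tree, k-nearest neighbour,
# support vector machine and naive Bayes on the 4-feature vectors, with
# confusion matrices on the spec'd 3-class problem (0 normal, 1 benign,
# 2 malignant). KNN and SVM see z-scored features (training-set statistics).

#' Classical classifier specification
#'
#' The hyperparameters are conventional defaults, surfaced explicitly:
#' knn k = 5; svm radial kernel with cost 1; decision tree with rpart
#' defaults; Gaussian naive Bayes.
#'
#' @param kind `"dt"`, `"knn"`, `"svm"` or `"nb"`.
#' @param k Neighbours for knn.
#' @param kernel,C SVM kernel and cost.
#' @param seed Integer seed (tree tie-breaks, SVM probability model).
#' @return List of class `"ClassifierSpec"`.
#' @export
classifierSpec <- function(kind = c("dt", "knn", "svm", "nb"),
                           k = 5L, kernel = "radial", C = 1, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "knn" && k < 1L) stop("k must be >= 1")
  if (kind == "svm" && C <= 0) stop("C must be > 0")
  structure(list(kind = kind, k = as.integer(k), kernel = kernel, C = C,
                 seed = as.integer(seed)), class = "ClassifierSpec")
}

asFeatureMatrix <- function(features) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("non-finite feature values")
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

#' Train a classical classifier
#'
#' @param spec A [classifierSpec()].
#' @param features Numeric matrix or data.frame, one row per sample.
#' @param labels Class labels (coerced to factor; for the 3-class problem
#'   use 0 = normal, 1 = benign, 2 = malignant).
#' @return A [FittedClassifier-class].
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 5), 20))
#' y <- rep(0:1, each = 20)
#' fc <- trainClassifier(classifierSpec("nb"), x, y)
#' accuracyFromConfusion(evaluateClassifier(fc, x, y))
#' @export
trainClassifier <- function(spec, features, labels) {
  stopifnot(inherits(spec, "ClassifierSpec"))
  x <- asFeatureMatrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("need at least 2 classes in the training labels")
  if (any(table(y) < 1L)) stop("degenerate training set")
  center <- scale_ <- numeric(0)
  if (spec$kind %in% c("knn", "svm")) {
    center <- colMeans(x)
    scale_ <- apply(x, 2L, sd)
    scale_[scale_ == 0] <- 1
    x <- sweep(sweep(x, 2L, center), 2L, scale_, "/")
  }
  fit <- withr::with_seed(spec$seed, switch(spec$kind,
    dt = {
      d <- data.frame(y = y, x)
      rpart::rpart(y ~ ., data = d, method = "class")
    },
    knn = caret::knn3(x, y, k = min(spec$k, nrow(x))),
    svm = e1071::svm(x, y, kernel = spec$kernel, cost = spec$C,
                     probability = TRUE),
    nb = e1071::naiveBayes(x, y)))
  new("FittedClassifier", kind = spec$kind, fit = fit, center = center,
      scale = scale_, levels = levels(y), spec = unclass(spec))
}

applyScaling <- function(fc, x) {
  if (length(fc@center))
    x <- sweep(sweep(x, 2L, fc@center), 2L, fc@scale, "/")
  x
}

#' Predict class labels / class probabilities
#'
#' `predictScores` returns an n x C matrix of class probabilities with one
#' column per training class; `predictLabels` the factor of hard labels
#' (argmax of the probabilities, model-native prediction where available).
#'
#' @param fc A [FittedClassifier-class].
#' @param features Feature matrix with the training columns.
#' @return Factor of labels / numeric matrix of probabilities.
#' @export
predictLabels <- function(fc, features) {
  p <- predictScores(fc, features)
  factor(fc@levels[max.col(p, ties.method = "first")], levels = fc@levels)
}

#' @rdname predictLabels
#' @export
predictScores <- function(fc, features) {
  stopifnot(is(fc, "FittedClassifier"))
  x <- asFeatureMatrix(features)
  x <- applyScaling(fc, x)
  p <- switch(fc@kind,
    dt = predict(fc@fit, newdata = data.frame(x), type = "prob"),
    knn = predict(fc@fit, x, type = "prob"),
    svm = {
      pr <- predict(fc@fit, x, probability = TRUE)
      attr(pr, "probabilities")
    },
    nb = predict(fc@fit, x, type = "raw"))
  p <- p[, fc@levels, drop = FALSE]
  rownames(p) <- NULL
  as.matrix(p)
}

#' Evaluate a classifier into a confusion matrix
#'
#' Rows are true classes, columns predicted classes; the total equals the
#' number of evaluated samples.
#'
#' @param fc A [FittedClassifier-class].
#' @param features Feature matrix.
#' @param labels True labels.
#' @return Integer C x C matrix with dimnames `true` x `predicted`.
#' @export
evaluateClassifier <- function(fc, features, labels) {
  pred <- predictLabels(fc, features)
  confusionCounts(factor(labels, levels = fc@levels), pred, fc@levels)
}

#' Tally a confusion matrix from label vectors
#'
#' @param truth,pred Vectors of true and predicted labels.
#' @param levels Class levels fixing row/column order.
#' @return Integer matrix, rows = true class, cols = predicted class.
#' @export
confusionCounts <- function(truth, pred, levels = sort(unique(c(as.character(truth), as.character(pred))))) {
  if (length(truth) != length(pred)) stop("label length mismatch")
  tt <- table(true = factor(truth, levels = levels),
              predicted = factor(pred, levels = levels))
  m <- matrix(as.integer(tt), nrow = length(levels),
              dimnames = list(true = levels, predicted = levels))
  m
}
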