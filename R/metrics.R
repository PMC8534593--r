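# Confusion-matrix metrics, ROC/AUC by threshold sweep, per-image
# segmentation AUC and the AUC-above-cutoff summary. Zero denominators are
# an explicit error, never a silent zero.

#' Binary confusion counts
#'
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @return Named integer vector of class `"binaryCounts"`.
#' @examples
#' sensitivity(binaryCounts(TP = 116, FP = 0, TN = 0, FN = 15))
#' @export
binaryCounts <- function(TP, FP, TN, FN) {
  v <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(v < 0)) stop("counts must be non-negative")
  if (sum(v) == 0) stop("total count must be positive")
  structure(as.integer(v), names = names(v), class = "binaryCounts")
}

metricRatio <- function(num, den, what) {
  if (den == 0) stop("undefined metric: zero denominator in ", what)
  num / den
}

#' Confusion-matrix metrics
#'
#' `sensitivity` = TP / (TP + FN); `precision` = TP / (TP + FP);
#' `accuracy` = (TN + TP) / (FP + TN + FN + TP). `specificity`
#' (TN / (TN + FP)) is provided as an addition for completeness.
#'
#' @param c Counts from [binaryCounts()] or [oneVsRestCounts()].
#' @return A fraction in \[0, 1\]; a zero denominator is an error.
#' @export
sensitivity <- function(c) metricRatio(c[["TP"]], c[["TP"]] + c[["FN"]], "sensitivity")

#' @rdname sensitivity
#' @export
precision <- function(c) metricRatio(c[["TP"]], c[["TP"]] + c[["FP"]], "precision")

#' @rdname sensitivity
#' @export
accuracy <- function(c) metricRatio(c[["TN"]] + c[["TP"]], sum(unclass(c)), "accuracy")

#' @rdname sensitivity
#' @export
specificity <- function(c) metricRatio(c[["TN"]], c[["TN"]] + c[["FP"]], "specificity")

#' One-vs-rest reduction of a multi-class confusion matrix
#'
#' TP is the diagonal entry of the positive class, FN its row remainder, FP
#' its column remainder, TN everything else; the four counts always sum to
#' the matrix total.
#'
#' @param cm Square count matrix, rows = true class, cols = predicted.
#' @param positive Row/column name or index of the positive class.
#' @return A [binaryCounts()] vector.
#' @export
oneVsRestCounts <- function(cm, positive) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  i <- if (is.character(positive)) match(positive, rownames(cm)) else as.integer(positive)
  if (is.na(i) || i < 1 || i > nrow(cm)) stop("unknown class: ", positive)
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- sum(cm) - tp - fn - fp
  binaryCounts(TP = tp, FP = fp, TN = tn, FN = fn)
}

#' ROC curve by threshold sweep
#'
#' Sweeps the unique score values as thresholds (ties grouped), yielding
#' monotone FPR/TPR sequences from (0, 0) to (1, 1); the AUC is the
#' trapezoidal area under the curve, which equals the Mann-Whitney
#' concordance statistic with ties counted 1/2.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param truth Binary truth (logical, or 0/1).
#' @return List of class `"rocCurve"`: `fpr`, `tpr`, `thresholds`, `auc`.
#' @examples
#' rocCurve(c(.9, .8, .7, .6, .4, .2), c(1, 1, 0, 1, 0, 0))$auc
#' @export
rocCurve <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth)) stop("length mismatch")
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; t <- truth[o]
  grp_last <- which(diff(s) != 0)
  grp_last <- c(grp_last, length(s))
  ctp <- cumsum(t)[grp_last]
  cfp <- cumsum(!t)[grp_last]
  tpr <- c(0, ctp / n_pos)
  fpr <- c(0, cfp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, s[grp_last]), auc = auc),
            class = "rocCurve")
}

#' Per-image segmentation AUC
#'
#' Treats the pixels of one image as ROC samples: ground-truth tumor pixels
#' (mask value 255, 225 accepted) are positives and the predicted
#' probability map provides the scores.
#'
#' @param prob_map Numeric matrix of tumor probabilities.
#' @param gt_mask Integer ground-truth mask; must contain at least one tumor
#'   and one non-tumor pixel.
#' @return AUC in \[0, 1\].
#' @export
perImageAuc <- function(prob_map, gt_mask) {
  stopifnot(all(dim(prob_map) == dim(gt_mask)))
  pos <- decodeMask(gt_mask)$tumor
  if (!any(pos) || all(pos))
    stop("single-class ground truth: per-image AUC undefined")
  rocCurve(as.vector(prob_map), as.vector(pos))$auc
}

#' Fraction of images above an AUC cutoff
#'
#' Summarizes per-image AUCs as the fraction strictly above `cutoff`
#' (default 0.6, the conventional high-performance boundary). NA entries
#' (images excluded for single-class ground truth) are dropped with a
#' message.
#'
#' @param aucs Numeric vector of per-image AUCs (NAs allowed).
#' @param cutoff AUC cutoff.
#' @return Fraction in \[0, 1\].
#' @examples
#' aucSummary(c(0.9, 0.7, 0.5, 0.3))  # 0.5
#' @export
aucSummary <- function(aucs, cutoff = 0.6) {
  if (anyNA(aucs)) {
    message(sum(is.na(aucs)), " image(s) excluded (single-class ground truth)")
    aucs <- aucs[!is.na(aucs)]
  }
  if (!length(aucs)) stop("no usable per-image AUCs")
  mean(aucs > cutoff)
}

#' Accuracy straight from a confusion matrix
#'
#' trace / total; exact equality with `mean(pred == true)` by construction.
#'
#' @param cm Square count matrix.
#' @return Fraction in \[0, 1\].
#' @export
accuracyFromConfusion <- function(cm) {
  cm <- as.matrix(cm)
  sum(diag(cm)) / sum(cm)
}

#' Format a fraction as a percentage at one decimal place
#'
#' @param x Fraction in \[0, 1\].
#' @return Numeric percentage rounded to 1 decimal (e.g. 0.8855 -> 88.5).
#' @export
asPercent <- function(x) round(100 * x, 1)
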