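#' Build a confusion matrix (rows = predicted, columns = actual)
#'
#' The table orientation follows the reporting convention of slide-grading
#' studies: each row is a predicted class, each column an actual class.
#'
#' @param predicted,actual vectors of class names (or ordinal codes 1..3).
#' @param classes class order; defaults to the ordinal classes, with
#'   `"OTHERS"` appended automatically when present in the data.
#' @return an integer matrix of class `cg_confusion` with `dimnames`
#'   `list(predicted, actual)`.
#' @export
confusion_matrix <- function(predicted, actual, classes = NULL) {
  predicted <- label_name(predicted)
  actual <- label_name(actual)
  if (is.null(classes)) {
    classes <- cg_classes()
    if (any(c(predicted, actual) == "OTHERS")) classes <- cg_all_classes()
  }
  stopifnot(all(predicted %in% classes), all(actual %in% classes),
            length(predicted) == length(actual))
  cm <- table(factor(predicted, classes), factor(actual, classes))
  as_confusion_matrix(matrix(as.integer(cm), nrow = length(classes),
                             dimnames = list(classes, classes)))
}

#' @rdname confusion_matrix
#' @param x a square numeric matrix of counts, rows = predicted,
#'   columns = actual, with class names as `rownames`.
#' @export
as_confusion_matrix <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == ncol(x), all(x >= 0), !is.null(rownames(x)))
  if (is.null(colnames(x))) colnames(x) <- rownames(x)
  stopifnot(identical(rownames(x), colnames(x)))
  names(dimnames(x)) <- c("predicted", "actual")
  structure(x, class = c("cg_confusion", "matrix", "array"))
}

#' @export
print.cg_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = predicted, columns = actual), n =",
      sum(x), "\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Balanced accuracy: unweighted mean of per-class recall
#'
#' @param cm a `cg_confusion` matrix.
#' @return a single value in \[0, 1\].
#' @export
balanced_accuracy <- function(cm) {
  support <- colSums(cm)
  if (any(support == 0))
    stop("balanced accuracy undefined: actual class with zero items: ",
         paste(colnames(cm)[support == 0], collapse = ", "))
  mean(diag(as.matrix(cm)) / support)
}

#' Support-weighted precision, sensitivity and F1
#'
#' Per-class precision = correct / predicted-total, sensitivity (recall) =
#' correct / actual-total, F1 = their harmonic mean; each is then averaged
#' with the actual-class supports as weights. Per-class values with a zero
#' denominator are defined as 0 and flagged in the `degenerate` field.
#' Weighted sensitivity is algebraically the micro accuracy (trace / total).
#'
#' @param cm a `cg_confusion` matrix.
#' @return list with `precision`, `sensitivity`, `f1`, a `per_class`
#'   data frame, and `degenerate` (TRUE when a zero denominator occurred).
#' @export
weighted_prf <- function(cm) {
  cm <- as.matrix(cm)
  if (sum(cm) == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  pred_tot <- rowSums(cm)
  act_tot <- colSums(cm)
  degenerate <- any(pred_tot == 0) || any(act_tot == 0)
  prec <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  rec <- ifelse(act_tot > 0, tp / act_tot, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- act_tot / sum(cm)
  list(precision = sum(w * prec), sensitivity = sum(w * rec),
       f1 = sum(w * f1),
       per_class = data.frame(class = rownames(cm), precision = prec,
                              sensitivity = rec, f1 = f1,
                              support = as.integer(act_tot),
                              row.names = NULL),
       degenerate = degenerate)
}

#' Quadratic weighted kappa of an ordinal confusion matrix
#'
#' Chance-corrected agreement with quadratic distance weights
#' `w[y, yhat] = (y - yhat)^2 / (n - 1)^2`; the expected matrix is the
#' outer product of the marginals normalised to the observed total.
#' Only defined on the ordered grades, so a matrix containing `"OTHERS"`
#' is rejected (use [exclude_class()] first).
#'
#' @param cm a `cg_confusion` matrix over ordered classes.
#' @return kappa in \[-1, 1\].
#' @export
qwk_statistic <- function(cm) {
  cm <- as.matrix(cm)
  if ("OTHERS" %in% rownames(cm))
    stop("quadratic weighted kappa is undefined for the unordered OTHERS class")
  k <- nrow(cm)
  stopifnot(k >= 2)
  w <- qwk_weight_matrix(k)
  m <- outer(rowSums(cm), colSums(cm)) / sum(cm)
  1 - sum(w * cm) / sum(w * m)
}

#' Drop a class from evaluation
#'
#' Removes both the predicted row and the actual column of `class`: items of
#' the dropped class disappear, and items of other classes that were
#' predicted as the dropped class are removed from the evaluation as well.
#'
#' @param cm a `cg_confusion` matrix.
#' @param class class name to exclude.
#' @export
exclude_class <- function(cm, class) {
  stopifnot(class %in% rownames(cm))
  keep <- setdiff(rownames(cm), class)
  as_confusion_matrix(as.matrix(cm)[keep, keep, drop = FALSE])
}

#' Pixel-level segmentation metrics
#'
#' Dice, intersection-over-union, sensitivity, precision and accuracy
#' between a predicted and a reference binary mask. Two empty masks count
#' as perfect agreement (Dice = IoU = 1), and any per-metric zero
#' denominator is likewise resolved to 1 (nothing to miss).
#'
#' @param pred,truth binary masks (0/1, logical, or 0/255) of equal shape.
#' @return named list of the five metrics.
#' @export
segmentation_metrics <- function(pred, truth) {
  stopifnot(all(dim(pred) == dim(truth)))
  p <- pred > 0
  t <- truth > 0
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  safe <- function(num, den) if (den == 0) 1 else num / den
  list(dice = safe(2 * tp, 2 * tp + fp + fn),
       iou = safe(tp, tp + fp + fn),
       sensitivity = safe(tp, tp + fn),
       precision = safe(tp, tp + fp),
       accuracy = (tp + tn) / length(p))
}

#' Balanced accuracy of epithelium detection
#'
#' Scores the binary decision "does this slide contain epithelium?" as the
#' mean of the positive and the negative recall. A slide counts as a
#' predicted positive whenever the pipeline finds any epithelium (i.e. its
#' diagnosis is not `"OTHERS"`).
#'
#' @param predicted_positive,actual_positive logical vectors.
#' @export
detection_balanced_accuracy <- function(predicted_positive, actual_positive) {
  stopifnot(length(predicted_positive) == length(actual_positive),
            any(actual_positive), any(!actual_positive))
  tpr <- mean(predicted_positive[actual_positive])
  tnr <- mean(!predicted_positive[!actual_positive])
  (tpr + tnr) / 2
}

#' One-vs-rest macro AUC
#'
#' Rank-based (Mann-Whitney) AUC of each class against the rest, averaged
#' over classes. Provided for completeness; requires per-item class scores.
#'
#' @param scores numeric matrix, one row per item, one column per class.
#' @param actual actual class names or codes, matching `colnames(scores)`.
#' @export
macro_auc <- function(scores, actual) {
  actual <- label_name(actual)
  stopifnot(nrow(scores) == length(actual), !is.null(colnames(scores)))
  aucs <- vapply(colnames(scores), function(cl) {
    pos <- actual == cl
    if (!any(pos) || all(pos)) return(NA_real_)
    r <- rank(scores[, cl])
    n1 <- sum(pos)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * (length(pos) - n1))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Full evaluation report for a confusion matrix
#'
#' Balanced accuracy, support-weighted precision/sensitivity/F1 and, when
#' the matrix holds only the ordered grades, the quadratic weighted kappa.
#'
#' @param cm a `cg_confusion` matrix.
#' @return list of metrics plus the per-class table.
#' @export
metrics_report <- function(cm) {
  prf <- weighted_prf(cm)
  list(balanced_accuracy = balanced_accuracy(cm),
       qwk = if ("OTHERS" %in% rownames(cm)) NA_real_ else qwk_statistic(cm),
       precision_weighted = prf$precision,
       sensitivity_weighted = prf$sensitivity,
       f1_weighted = prf$f1,
       per_class = prf$per_class,
       n = sum(cm))
}
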