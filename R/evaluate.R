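#' Confusion counts at a score threshold
#'
#' A case is predicted positive when its score is at least `threshold`
#' (default 0.5). Labels are 0 (non-malignant) and 1 (malignant).
#'
#' @param labels Integer vector of 0/1 labels.
#' @param scores Numeric scores, same length.
#' @param threshold Decision threshold.
#' @return An object of class `confusion_counts` with fields `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores))
    stopf("labels and scores differ in length")
  if (length(labels) && !all(labels %in% c(0, 1)))
    stopf("labels must be 0 or 1")
  pred <- scores >= threshold
  structure(list(
    TP = sum(pred & labels == 1), TN = sum(!pred & labels == 0),
    FP = sum(pred & labels == 0), FN = sum(!pred & labels == 1)
  ), class = "confusion_counts")
}

#' Classification accuracy, in percent
#'
#' `100 * (TP + TN) / (TP + FP + TN + FN)`.
#'
#' @param counts A `confusion_counts`.
#' @return Accuracy on the 0-100 scale.
#' @export
accuracy <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) stopf("accuracy undefined: no evaluated cases")
  100 * (counts$TP + counts$TN) / total
}

#' Sensitivity and specificity, in percent
#'
#' `SE = 100 * TP / (TP + FN)` (proportion of actual positives identified);
#' `SP = 100 * TN / (FP + TN)` (proportion of actual negatives identified).
#' An empty class makes the corresponding metric undefined and is reported as
#' an error rather than silently returned as 0.
#'
#' @param counts A `confusion_counts`.
#' @return Named vector `c(SE = ..., SP = ...)` on the 0-100 scale.
#' @export
sensitivity_specificity <- function(counts) {
  if (counts$TP + counts$FN == 0)
    stopf("sensitivity undefined: no positive cases")
  if (counts$TN + counts$FP == 0)
    stopf("specificity undefined: no negative cases")
  c(SE = 100 * counts$TP / (counts$TP + counts$FN),
    SP = 100 * counts$TN / (counts$FP + counts$TN))
}

#' ROC curve and area under it (AUOC)
#'
#' Sweeps the decision threshold over the distinct scores (ties grouped into
#' one step), tracing sensitivity against the false-positive rate `1 - SP`.
#' The area is computed by trapezoidal integration and reported on the 0-100
#' scale; with grouped ties it equals the Mann-Whitney pair-counting
#' statistic times 100.
#'
#' @param labels 0/1 labels; both classes must be present.
#' @param scores Numeric scores.
#' @return A list with `curve` (data frame with columns `fpr`, `tpr`, from
#'   (0,0) to (1,1)) and `auoc`.
#' @export
roc_auoc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stopf("labels and scores differ in length")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stopf("ROC undefined: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- c(s[-length(s)] != s[-1L], TRUE)   # last index of each tie group
  tpr <- c(0, cumsum(l == 1)[keep] / npos)
  fpr <- c(0, cumsum(l == 0)[keep] / nneg)
  auoc <- 100 * sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr), auoc = auoc)
}

#' All four run metrics from labels and scores
#'
#' @param labels 0/1 labels.
#' @param scores Numeric scores.
#' @param threshold Decision threshold for AC/SE/SP.
#' @return Named vector `c(AC, SE, SP, AUOC)` on the 0-100 scale.
#' @export
run_metrics <- function(labels, scores, threshold = 0.5) {
  counts <- confusion_counts(labels, scores, threshold)
  sesp <- sensitivity_specificity(counts)
  c(AC = accuracy(counts), sesp, AUOC = roc_auoc(labels, scores)$auoc)
}
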