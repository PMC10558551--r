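# Utility metrics: accuracy and F1 from confusion counts, plus a convenience
# model evaluator.

#' Confusion counts
#'
#' `confusion_matrix()` tabulates a C x C confusion table (rows = truth,
#' columns = prediction, classes `0..C-1`); `binary_counts()` builds the 2 x 2
#' table from TP/TN/FP/FN with class 1 as the positive class.
#'
#' @param truth,pred integer class vectors in `0..C-1`.
#' @param num_classes declared class count.
#' @return an integer matrix of class `confusion_counts`.
#' @export
confusion_matrix <- function(truth, pred, num_classes) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  C <- as.integer(num_classes)
  if (length(truth) != length(pred)) stop("truth and pred differ in length")
  if (length(truth) > 0 && (min(c(truth, pred)) < 0L || max(c(truth, pred)) >= C)) {
    stop("classes must lie in 0..", C - 1L)
  }
  cm <- matrix(0L, C, C, dimnames = list(truth = 0:(C - 1L), pred = 0:(C - 1L)))
  for (i in seq_along(truth)) cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  structure(cm, class = c("confusion_counts", "matrix", "array"))
}

#' @rdname confusion_matrix
#' @param TP,TN,FP,FN non-negative binary confusion counts (positive = class 1).
#' @export
binary_counts <- function(TP, TN, FP, FN) {
  if (any(c(TP, TN, FP, FN) < 0)) stop("counts must be non-negative")
  cm <- matrix(as.integer(c(TN, FN, FP, TP)), 2L, 2L,
               dimnames = list(truth = 0:1, pred = 0:1))
  structure(cm, class = c("confusion_counts", "matrix", "array"))
}

#' Classification accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)` in the binary case; the trace of the
#' confusion table over its total in general.
#'
#' @param counts a `confusion_counts` table.
#' @return accuracy in `[0, 1]`.
#' @examples
#' accuracy(binary_counts(TP = 9, TN = 8, FP = 1, FN = 2))  # 0.85
#' @export
accuracy <- function(counts) {
  total <- sum(counts)
  if (total == 0) stop("empty confusion table")
  sum(diag(counts)) / total
}

# one-vs-rest F1 of class `cl` (1-based index into the table)
class_f1 <- function(cm, cl) {
  tp <- cm[cl, cl]
  fp <- sum(cm[-cl, cl])
  fn <- sum(cm[cl, -cl])
  den <- 2 * tp + fp + fn
  if (den == 0) {
    warning("F1 undefined for class ", cl - 1L, " (no positives anywhere); defined as 0")
    return(0)
  }
  2 * tp / den
}

#' F1 score
#'
#' Binary F1 is `2 TP / (2 TP + FP + FN)` with class 1 as positive. For
#' multiclass tables, per-class one-vs-rest F1 values are combined by a
#' macro (unweighted mean, the headline value) or support-weighted average.
#' An undefined denominator yields 0 with a warning.
#'
#' @param counts a `confusion_counts` table.
#' @param average `"binary"`, `"macro"` or `"weighted"`. `"binary"` is only
#'   valid for 2 x 2 tables.
#' @return F1 in `[0, 1]`.
#' @examples
#' f1(binary_counts(TP = 9, TN = 8, FP = 1, FN = 2))  # 18/21
#' @export
f1 <- function(counts, average = c("binary", "macro", "weighted")) {
  average <- match.arg(average)
  C <- nrow(counts)
  if (average == "binary") {
    if (C != 2L) stop("binary F1 requires a 2x2 table; use macro or weighted")
    return(class_f1(counts, 2L))
  }
  per <- vapply(seq_len(C), function(cl) class_f1(counts, cl), numeric(1))
  if (average == "macro") return(mean(per))
  support <- rowSums(counts)
  if (sum(support) == 0) stop("empty confusion table")
  sum(per * support) / sum(support)
}

#' Evaluate a model on a labeled dataset
#'
#' @param model an `afs_model` (or SISA wrapper).
#' @param data a [labeled_dataset()].
#' @return a list with `accuracy`, `f1_macro`, `f1_weighted` and the
#'   `confusion` table.
#' @export
evaluate_model <- function(model, data) {
  pred <- predict(model, data, type = "class")
  cm <- confusion_matrix(data$labels, pred, data$num_classes)
  list(accuracy = accuracy(cm),
       f1_macro = f1(cm, "macro"),
       f1_weighted = f1(cm, "weighted"),
       confusion = cm)
}
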