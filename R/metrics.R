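# Per-sample membership signals: a model is typically more accurate, more
# confident and lower-entropy on its own training samples than on unseen
# ones. These three scores are the raw material of the audit.

check_prob_row <- function(prob_row) {
  prob_row <- as.numeric(prob_row)
  if (any(prob_row < 0)) stop("probability vector has negative entries")
  if (abs(sum(prob_row) - 1) > 1e-6) stop("probability vector does not sum to 1")
  prob_row
}

check_label <- function(y, C) {
  y <- as.integer(y)
  if (is.na(y) || y < 0L || y >= C) stop("label must lie in 0..", C - 1L)
  y
}

#' Correctness of a single prediction
#'
#' 1 if the arg-max class of the probability vector equals the true label
#' (ties broken towards the lowest class index), else 0.
#'
#' @param prob_row probability vector over the C classes (sums to 1).
#' @param y true class index in `0..C-1`.
#' @return 0 or 1.
#' @examples
#' correctness(c(0.1, 0.9), 1)  # 1
#' @export
correctness <- function(prob_row, y) {
  prob_row <- check_prob_row(prob_row)
  y <- check_label(y, length(prob_row))
  as.integer(which.max(prob_row) - 1L == y)
}

#' Probability assigned to the true class
#'
#' @inheritParams correctness
#' @return the true-class probability in `[0, 1]`.
#' @examples
#' true_label_confidence(c(0.2, 0.5, 0.3), 2)  # 0.3
#' @export
true_label_confidence <- function(prob_row, y) {
  prob_row <- check_prob_row(prob_row)
  y <- check_label(y, length(prob_row))
  prob_row[y + 1L]
}

#' Shannon entropy of a prediction
#'
#' Natural-log entropy `-sum(p * log p)` with `0 * log 0 := 0`; ranges from 0
#' (one-hot) to `log(C)` (uniform).
#'
#' @param prob_row probability vector over the C classes.
#' @return a non-negative number.
#' @examples
#' prediction_entropy(rep(0.25, 4))  # log(4)
#' @export
prediction_entropy <- function(prob_row) {
  prob_row <- check_prob_row(prob_row)
  lp <- ifelse(prob_row > 0, log(prob_row), 0)
  -sum(prob_row * lp)
}

#' Per-sample membership metrics of a model over a dataset
#'
#' Runs the model on every sample and records the three membership signals
#' (correctness, true-label confidence, prediction entropy), one row per
#' sample in dataset order.
#'
#' @param model an `afs_model` (or anything with a conforming
#'   [predict_proba()] matrix output).
#' @param data a [labeled_dataset()] with the same declared class count.
#' @return a `metric_matrix`: a data frame with columns `id`, `label`,
#'   `correctness`, `confidence`, `entropy` and attribute `num_classes`.
#' @export
metric_matrix <- function(model, data) {
  stopifnot(inherits(data, "labeled_dataset"))
  C <- if (inherits(model, "afs_model")) model$spec$num_classes else ncol(predict_proba(model, data))
  if (C != data$num_classes) {
    stop("model has ", C, " classes but data declares ", data$num_classes)
  }
  p <- predict_proba(model, data)
  if (nrow(p) != n_samples(data) || ncol(p) != C) stop("unexpected probability matrix shape")
  n <- n_samples(data)
  out <- data.frame(
    id = data$ids,
    label = data$labels,
    correctness = as.integer(row_argmax(p) == data$labels),
    confidence = p[cbind(seq_len(n), data$labels + 1L)],
    entropy = row_entropy(p),
    stringsAsFactors = FALSE)
  attr(out, "num_classes") <- C
  class(out) <- c("metric_matrix", class(out))
  out
}
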