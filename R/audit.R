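# Dataset-level membership audit: per-sample OR-rule votes over the three
# calibrated metrics, then a pooled two-sample Student's t-test of the vote
# vector against an all-one reference vector. A large p-value means the
# query is indistinguishable from training data (member-like).

#' Membership vote for a single sample
#'
#' A sample is voted a member iff at least one metric lands on the member
#' side of its threshold: the prediction is correct, OR the true-label
#' confidence is `>=` its class threshold, OR the prediction entropy is `<=`
#' its class threshold.
#'
#' @param correctness 0/1 correctness indicator ([correctness()]).
#' @param confidence true-label confidence ([true_label_confidence()]).
#' @param entropy prediction entropy ([prediction_entropy()]).
#' @param y class index of the sample.
#' @param thresholds a `threshold_set` from [calibrate()] / [infer_thresholds()].
#' @return 0 or 1.
#' @export
sample_membership <- function(correctness, confidence, entropy, y, thresholds) {
  as.integer(correctness >= thresholds$correctness$threshold |
               confidence >= resolve_threshold(thresholds, "confidence", y) |
               entropy <= resolve_threshold(thresholds, "entropy", y))
}

#' Per-sample membership votes for a metric matrix
#'
#' Vectorised OR-rule aggregation with a per-metric breakdown.
#'
#' @param mm a [metric_matrix()].
#' @param thresholds a `threshold_set`.
#' @return a data frame with columns `id`, `vote` and the three per-metric
#'   indicator columns `vote_correctness`, `vote_confidence`, `vote_entropy`.
#' @export
membership_votes <- function(mm, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  tau_conf <- vapply(mm$label, function(y) resolve_threshold(thresholds, "confidence", y), numeric(1))
  tau_ent <- vapply(mm$label, function(y) resolve_threshold(thresholds, "entropy", y), numeric(1))
  vc <- as.integer(mm$correctness >= thresholds$correctness$threshold)
  vf <- as.integer(mm$confidence >= tau_conf)
  ve <- as.integer(mm$entropy <= tau_ent)
  data.frame(id = mm$id, vote = as.integer(vc | vf | ve),
             vote_correctness = vc, vote_confidence = vf, vote_entropy = ve,
             stringsAsFactors = FALSE)
}

#' Dataset-level audit p-value
#'
#' Pooled-variance two-sample Student's t-test, two-tailed, comparing the
#' membership vote vector to an all-one reference vector of the same length N
#' (df = 2N - 2). Degenerate cases are defined explicitly: a vote vector
#' identical to the reference (all ones) gives p = 1; zero pooled variance
#' with unequal means (all zeros) gives p = 0.
#'
#' @param votes numeric 0/1 vote vector (or a [membership_votes()] data frame).
#' @return a p-value in `[0, 1]`; large values are member-like.
#' @examples
#' audit_pvalue(rep(1, 50))           # 1
#' audit_pvalue(rep(c(1, 0), c(80, 20)))
#' @export
audit_pvalue <- function(votes) {
  if (is.data.frame(votes)) votes <- votes$vote
  votes <- as.numeric(votes)
  n <- length(votes)
  if (n == 0L) stop("empty membership vector")
  m <- mean(votes)
  ss <- sum((votes - m)^2)          # reference all-one vector contributes 0
  sp2 <- ss / (2 * n - 2)
  if (n == 1L || sp2 == 0) {
    return(if (m == 1) 1 else 0)
  }
  tstat <- (m - 1) / sqrt(sp2 * 2 / n)
  2 * stats::pt(-abs(tstat), df = 2 * n - 2)
}

#' Audit whether a query dataset was used to train a model
#'
#' The full audit pipeline: calibrate thresholds on the calibration dataset
#' (unless a precomputed `threshold_set` is supplied), score the query on the
#' target model, aggregate per-sample OR-rule votes, and test the vote vector
#' against the all-one reference. Deterministic under fixed seeds.
#'
#' @param target the target `afs_model` under audit.
#' @param query a `query_dataset` or [labeled_dataset()].
#' @param calibration a [labeled_dataset()] disjoint from the target's
#'   training data (ignored when `thresholds` is given).
#' @param arch [model_spec()] for the shadow model (defaults to the target's
#'   spec; conventionally the student architecture).
#' @param alpha user-defined significance level for the verdict.
#' @param thresholds optional precomputed `threshold_set`.
#' @param epochs,lr,batch_size shadow-model training hyperparameters.
#' @param seed integer seed.
#' @return an object of class `afs_audit`: fields `p_value`, `alpha`,
#'   `verdict` (`"member-like"` if `p >= alpha`), `votes`, `member_fraction`,
#'   `per_metric_vote_rates`, `n_query`, `low_power` (TRUE when N < 20),
#'   `thresholds`, `seed`.
#' @export
audit_dataset <- function(target, query, calibration = NULL, arch = NULL,
                          alpha = 0.05, thresholds = NULL,
                          epochs = 50L, lr = 0.01, batch_size = 32L, seed = 0L) {
  qdata <- if (inherits(query, "query_dataset")) query$data else query
  stopifnot(inherits(qdata, "labeled_dataset"))
  if (n_samples(qdata) == 0L) stop("empty query dataset")
  if (target$spec$num_classes != qdata$num_classes) {
    stop("target model and query disagree on the class count")
  }
  if (is.null(thresholds)) {
    if (is.null(calibration)) stop("either `calibration` or `thresholds` must be supplied")
    if (calibration$num_classes != qdata$num_classes) {
      stop("calibration and query disagree on the class count")
    }
    if (is.null(arch)) arch <- target$spec
    thresholds <- calibrate(arch, calibration, epochs = epochs, lr = lr,
                            batch_size = batch_size, seed = seed)
  }
  mm <- metric_matrix(target, qdata)
  votes <- membership_votes(mm, thresholds)
  p <- audit_pvalue(votes$vote)
  n <- nrow(votes)
  structure(list(
    p_value = p,
    alpha = alpha,
    verdict = if (p >= alpha) "member-like" else "non-member-like",
    votes = votes,
    member_fraction = mean(votes$vote),
    per_metric_vote_rates = c(correctness = mean(votes$vote_correctness),
                              confidence = mean(votes$vote_confidence),
                              entropy = mean(votes$vote_entropy)),
    n_query = n,
    low_power = n < 20L,
    thresholds = thresholds,
    target_fingerprint = model_fingerprint(target),
    seed = as.integer(seed)),
    class = "afs_audit")
}

#' @export
print.afs_audit <- function(x, ...) {
  cat("<afs_audit> N =", x$n_query,
      "| member fraction =", sprintf("%.3f", x$member_fraction),
      "| p =", format(x$p_value, digits = 4),
      "\n  verdict:", x$verdict, sprintf("(alpha = %g)", x$alpha))
  if (x$low_power) cat("  [low power: N < 20]")
  cat("\n")
  invisible(x)
}

#' @export
summary.afs_audit <- function(object, ...) {
  cat("Dataset membership audit\n")
  cat("  query size          :", object$n_query, "\n")
  cat("  member vote fraction:", sprintf("%.4f", object$member_fraction), "\n")
  cat("  per-metric rates    : correctness",
      sprintf("%.3f", object$per_metric_vote_rates[["correctness"]]),
      "| confidence", sprintf("%.3f", object$per_metric_vote_rates[["confidence"]]),
      "| entropy", sprintf("%.3f", object$per_metric_vote_rates[["entropy"]]), "\n")
  cat("  p-value (vs all-one):", format(object$p_value, digits = 6), "\n")
  cat("  verdict             :", object$verdict, sprintf("(alpha = %g)", object$alpha), "\n")
  if (object$low_power) cat("  note: N < 20, the two-sample test has low power\n")
  invisible(object)
}

#' Write an audit report as JSON
#'
#' @param audit an `afs_audit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_audit_json <- function(audit, path) {
  stopifnot(inherits(audit, "afs_audit"))
  obj <- list(p_value = audit$p_value, alpha = audit$alpha,
              verdict = audit$verdict, n_query = audit$n_query,
              member_fraction = audit$member_fraction,
              per_metric_vote_rates = as.list(audit$per_metric_vote_rates),
              low_power = audit$low_power,
              target_fingerprint = audit$target_fingerprint,
              seed = audit$seed,
              thresholds = unclass(audit$thresholds))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
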