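# Threshold calibration: a shadow ("calibration") model is trained on half of
# a calibration set that is disjoint from the target model's training data.
# Its training half provides known member scores, the untouched half known
# non-member scores, and per-metric, per-class thresholds are chosen to
# maximise balanced accuracy (TPR + TNR)/2 between the two populations.

#' Train the calibration (shadow) model
#'
#' Plain supervised training of the given architecture on the calibration
#' training half; deterministic under a fixed seed. `epochs = 0` returns the
#' freshly initialised, untrained model.
#'
#' @param arch a [model_spec()] for the shadow model (by convention the same
#'   architecture as the student under audit).
#' @param cal_train non-empty [labeled_dataset()].
#' @param epochs,lr,batch_size training hyperparameters.
#' @param seed integer seed.
#' @return an `afs_model`.
#' @export
train_calibration_model <- function(arch, cal_train, epochs = 50L, lr = 0.01,
                                    batch_size = 32L, seed = 0L) {
  stopifnot(inherits(arch, "model_spec"))
  if (!inherits(cal_train, "labeled_dataset") || n_samples(cal_train) == 0L) {
    stop("calibration training data must be a non-empty labeled_dataset")
  }
  if (arch$num_classes != cal_train$num_classes) {
    stop("architecture and calibration data disagree on the class count")
  }
  fit_classifier(arch, cal_train, epochs = epochs, lr = lr,
                 batch_size = batch_size, seed = seed)
}

#' Balanced accuracy of a threshold
#'
#' `TPR(t)` is the fraction of member scores on the member side of `t`
#' (`>= t` for direction `"ge"`, `<= t` for `"le"`); `TNR(t)` the fraction of
#' non-member scores on the other side. Returns their mean.
#'
#' @param t threshold.
#' @param member_scores,nonmember_scores non-empty numeric score vectors.
#' @param direction which side of `t` counts as member: `"ge"` or `"le"`.
#' @return a value in `[0, 1]`.
#' @examples
#' balanced_accuracy(0.5, c(0.9, 0.8), c(0.1, 0.2), "ge")  # 1
#' @export
balanced_accuracy <- function(t, member_scores, nonmember_scores,
                              direction = c("ge", "le")) {
  direction <- match.arg(direction)
  if (length(member_scores) == 0L || length(nonmember_scores) == 0L) {
    stop("score vectors must be non-empty")
  }
  if (direction == "ge") {
    tpr <- mean(member_scores >= t)
    tnr <- mean(nonmember_scores < t)
  } else {
    tpr <- mean(member_scores <= t)
    tnr <- mean(nonmember_scores > t)
  }
  (tpr + tnr) / 2
}

# Candidate grid: midpoints between consecutive sorted unique pooled scores,
# plus one sentinel below the minimum and one above the maximum. Finite and
# complete with respect to the achievable confusion tables.
threshold_candidates <- function(scores) {
  s <- sort(unique(scores))
  if (length(s) == 1L) return(c(s - 1, s + 1))
  c(s[1] - 1, (s[-length(s)] + s[-1]) / 2, s[length(s)] + 1)
}

# Exhaustive search over the candidate grid; smallest maximiser wins.
best_threshold <- function(member_scores, nonmember_scores, direction) {
  cand <- threshold_candidates(c(member_scores, nonmember_scores))
  bacc <- vapply(cand, balanced_accuracy, numeric(1),
                 member_scores = member_scores,
                 nonmember_scores = nonmember_scores, direction = direction)
  best <- which.max(bacc)  # candidates are sorted: first max = smallest maximiser
  list(threshold = cand[best], balanced_accuracy = bacc[best])
}

metric_directions <- c(confidence = "ge", entropy = "le")

#' Infer per-metric, per-class thresholds from calibration scores
#'
#' For the confidence (member side `>=`) and entropy (member side `<=`)
#' metrics, and for each class, selects the candidate threshold maximising
#' [balanced_accuracy()] between the class-conditional member and non-member
#' scores. Classes with fewer than `min_per_side` calibration samples on
#' either side fall back to the pooled-over-classes threshold. Correctness is
#' already binary and keeps a fixed threshold of 0.5 (member side `>=`).
#'
#' @param member_matrix,nonmember_matrix [metric_matrix()] data frames scored
#'   on known members / non-members of the calibration model.
#' @param min_per_side minimum per-class calibration samples per side before
#'   the pooled fallback is used (default 5).
#' @param provenance optional list recorded in the result (seed, fingerprints).
#' @return an object of class `threshold_set`.
#' @export
infer_thresholds <- function(member_matrix, nonmember_matrix,
                             min_per_side = 5L, provenance = list()) {
  if (nrow(member_matrix) == 0L || nrow(nonmember_matrix) == 0L) {
    stop("both metric matrices must be non-empty")
  }
  C <- attr(member_matrix, "num_classes") %||% (max(member_matrix$label, nonmember_matrix$label) + 1L)
  metrics <- list()
  for (m in names(metric_directions)) {
    dir <- metric_directions[[m]]
    pooled <- best_threshold(member_matrix[[m]], nonmember_matrix[[m]], dir)
    per_class <- rep(NA_real_, C)
    per_class_bacc <- rep(NA_real_, C)
    for (cl in 0:(C - 1L)) {
      ms <- member_matrix[[m]][member_matrix$label == cl]
      ns <- nonmember_matrix[[m]][nonmember_matrix$label == cl]
      if (length(ms) >= min_per_side && length(ns) >= min_per_side) {
        bt <- best_threshold(ms, ns, dir)
        per_class[cl + 1L] <- bt$threshold
        per_class_bacc[cl + 1L] <- bt$balanced_accuracy
      }
    }
    metrics[[m]] <- list(direction = dir, per_class = per_class,
                         per_class_balanced_accuracy = per_class_bacc,
                         fallback = pooled$threshold,
                         fallback_balanced_accuracy = pooled$balanced_accuracy)
  }
  structure(list(metrics = metrics,
                 correctness = list(threshold = 0.5, direction = "ge"),
                 num_classes = C, min_per_side = as.integer(min_per_side),
                 provenance = provenance),
            class = "threshold_set")
}

#' Resolve the threshold for a metric and class
#'
#' @param thresholds a `threshold_set`.
#' @param metric `"confidence"` or `"entropy"`.
#' @param y class index in `0..C-1`.
#' @return the class-specific threshold, or the pooled fallback when the
#'   class had too few calibration samples.
#' @export
resolve_threshold <- function(thresholds, metric, y) {
  stopifnot(inherits(thresholds, "threshold_set"))
  m <- thresholds$metrics[[metric]]
  if (is.null(m)) stop("unknown metric: ", metric)
  y <- check_label(y, thresholds$num_classes)
  v <- m$per_class[y + 1L]
  if (is.na(v)) v <- m$fallback
  if (is.na(v)) stop("no threshold resolvable for metric ", metric, ", class ", y)
  v
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set>", x$num_classes, "classes\n")
  for (m in names(x$metrics)) {
    mt <- x$metrics[[m]]
    side <- if (mt$direction == "ge") ">=" else "<="
    cat(sprintf("  %-11s member side %s | fallback %.4g | per-class set for %d/%d classes\n",
                m, side, mt$fallback, sum(!is.na(mt$per_class)), x$num_classes))
  }
  cat("  correctness fixed at >= 0.5\n")
  invisible(x)
}

#' Calibrate thresholds on a calibration dataset
#'
#' Implements the shadow-model protocol: the calibration set (disjoint from
#' the target model's training data) is split 50/50 into a calibration-train
#' and calibration-test half; a shadow model of the given architecture is
#' trained on the first half; member scores are its metrics on that half and
#' non-member scores its metrics on the untouched half; thresholds are then
#' inferred with [infer_thresholds()].
#'
#' @param arch a [model_spec()] for the shadow model.
#' @param calibration a [labeled_dataset()] with at least 2 samples.
#' @param epochs,lr,batch_size shadow-model training hyperparameters.
#' @param seed integer seed (controls the split and the training).
#' @param min_per_side per-class sample floor before the pooled fallback.
#' @return a `threshold_set` with provenance (seed and model fingerprint).
#' @export
calibrate <- function(arch, calibration, epochs = 50L, lr = 0.01,
                      batch_size = 32L, seed = 0L, min_per_side = 5L) {
  stopifnot(inherits(calibration, "labeled_dataset"))
  n <- n_samples(calibration)
  if (n < 2L) stop("calibration dataset must hold at least 2 samples")
  half <- n %/% 2L
  perm <- with_seed(derive_seed(seed, 11L), sample.int(n))
  cal_train <- dataset_subset(calibration, perm[seq_len(half)])
  cal_test <- dataset_subset(calibration, perm[(half + 1L):n])
  shadow <- train_calibration_model(arch, cal_train, epochs = epochs, lr = lr,
                                    batch_size = batch_size, seed = seed)
  member <- metric_matrix(shadow, cal_train)
  nonmember <- metric_matrix(shadow, cal_test)
  infer_thresholds(member, nonmember, min_per_side = min_per_side,
                   provenance = list(seed = as.integer(seed),
                                     shadow_fingerprint = model_fingerprint(shadow),
                                     n_member = n_samples(cal_train),
                                     n_nonmember = n_samples(cal_test)))
}

#' Serialize a threshold set to / from JSON
#'
#' @param thresholds a `threshold_set`.
#' @param path JSON file path.
#' @return `write_thresholds_json()` returns `path` invisibly;
#'   `read_thresholds_json()` returns a `threshold_set`.
#' @export
write_thresholds_json <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "threshold_set"))
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_thresholds_json
#' @export
read_thresholds_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (m in names(obj$metrics)) {
    obj$metrics[[m]]$per_class <- as.numeric(obj$metrics[[m]]$per_class)
    obj$metrics[[m]]$per_class_balanced_accuracy <-
      as.numeric(obj$metrics[[m]]$per_class_balanced_accuracy)
  }
  structure(obj, class = "threshold_set")
}
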