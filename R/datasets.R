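#' Construct a labeled dataset
#'
#' The basic container every split and query is drawn from: a feature matrix
#' (one row per sample; images are stored flattened with a `shape` attribute),
#' integer class labels in `0..C-1`, and unique stable sample identifiers.
#' The number of classes is declared, never inferred from the labels present.
#'
#' @param features numeric matrix, one row per sample. For image data attach
#'   `attr(features, "shape") <- c(H, W, C)`.
#' @param labels integer vector of class indices in `0..num_classes-1`.
#' @param num_classes declared number of classes C (>= 2).
#' @param ids optional character vector of unique sample ids; generated as
#'   `s000001, ...` when omitted.
#' @return an object of class `labeled_dataset`.
#' @examples
#' d <- labeled_dataset(matrix(rnorm(20), 10, 2), rep(0:1, 5), num_classes = 2)
#' nrow(d$features)
#' @export
labeled_dataset <- function(features, labels, num_classes, ids = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  n <- nrow(features)
  if (length(labels) != n) stop("features and labels disagree in length")
  num_classes <- as.integer(num_classes)
  if (num_classes < 2L) stop("`num_classes` must be >= 2")
  if (n > 0 && (min(labels) < 0L || max(labels) >= num_classes)) {
    stop("labels must lie in 0..", num_classes - 1L)
  }
  if (is.null(ids)) ids <- sprintf("s%06d", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("ids and features disagree in length")
  if (anyDuplicated(ids)) stop("sample ids must be unique")
  structure(list(ids = ids, features = features, labels = labels,
                 num_classes = num_classes),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset>", length(x$ids), "samples x", ncol(x$features),
      "features |", x$num_classes, "classes\n")
  invisible(x)
}

#' Number of samples in a labeled dataset
#' @param data a [labeled_dataset()].
#' @return integer sample count.
#' @export
n_samples <- function(data) length(data$ids)

#' Subset a labeled dataset
#'
#' @param data a [labeled_dataset()].
#' @param i integer indices or character sample ids.
#' @return a `labeled_dataset` holding the selected samples, in the order of `i`.
#' @export
dataset_subset <- function(data, i) {
  if (is.character(i)) {
    pos <- match(i, data$ids)
    if (anyNA(pos)) stop("unknown sample ids: ", paste(utils::head(i[is.na(pos)], 3), collapse = ", "))
    i <- pos
  }
  shp <- attr(data$features, "shape")
  feats <- data$features[i, , drop = FALSE]
  if (!is.null(shp)) attr(feats, "shape") <- shp
  labeled_dataset(feats, data$labels[i], data$num_classes, ids = data$ids[i])
}

# round half away from zero (used for the k*N member count of QM)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Split a pool into disjoint train / test / calibration sets
#'
#' Draws three pairwise-disjoint random subsets of the requested sizes without
#' replacement; whatever remains becomes a `holdout` partition that serves as
#' the non-member pool for [build_query()] (so non-members never leak into the
#' calibration model). Identical seeds give identical id sets.
#'
#' @param pool a [labeled_dataset()] to sample from.
#' @param train_n,test_n,cal_n requested split sizes.
#' @param seed integer seed.
#' @return an object of class `split_collection` with fields `train`, `test`,
#'   `calibration`, `holdout` and `seed`.
#' @examples
#' pool <- gen_gaussian_blobs(100, C = 2, d = 3, separation = 2, seed = 1)
#' sp <- make_splits(pool, 50, 20, 20, seed = 1)
#' length(intersect(sp$train$ids, sp$test$ids))  # 0
#' @export
make_splits <- function(pool, train_n, test_n, cal_n, seed = 0L) {
  stopifnot(inherits(pool, "labeled_dataset"))
  total <- train_n + test_n + cal_n
  n <- n_samples(pool)
  if (total > n) {
    stop("requested ", total, " samples but the pool holds only ", n,
         " (short by ", total - n, ")")
  }
  perm <- with_seed(seed, sample.int(n))
  tr <- perm[seq_len(train_n)]
  te <- perm[train_n + seq_len(test_n)]
  ca <- perm[train_n + test_n + seq_len(cal_n)]
  ho <- perm[seq.int(total + 1L, length.out = n - total)]
  structure(list(train = dataset_subset(pool, tr),
                 test = dataset_subset(pool, te),
                 calibration = dataset_subset(pool, ca),
                 holdout = dataset_subset(pool, ho),
                 seed = as.integer(seed)),
            class = "split_collection")
}

#' @export
print.split_collection <- function(x, ...) {
  cat("<split_collection> train:", n_samples(x$train),
      "| test:", n_samples(x$test),
      "| calibration:", n_samples(x$calibration),
      "| holdout:", n_samples(x$holdout), "\n")
  invisible(x)
}

#' Build a query dataset (QO, QNO, QM or QF)
#'
#' Query modes mirror the audit protocol: `QO` is drawn entirely from the
#' training split (overlap k = 1), `QNO` entirely from the held-out
#' non-member pool (k = 0), `QM` mixes `round(k*size)` members with
#' non-members (the realised overlap fraction is stored, computed by rounding
#' half away from zero), and `QF` -- the set designated to be forgotten -- is
#' drawn from the training split like `QO`.
#'
#' @param splits a [make_splits()] result.
#' @param mode one of `"QO"`, `"QNO"`, `"QM"`, `"QF"`.
#' @param size query size N.
#' @param k requested member fraction, `QM` only.
#' @param seed integer seed.
#' @return an object of class `query_dataset` with fields `data`, `mode`,
#'   `overlap_fraction`, `size`, `seed`.
#' @examples
#' pool <- gen_gaussian_blobs(300, C = 2, d = 3, separation = 2, seed = 1)
#' sp <- make_splits(pool, 100, 50, 50, seed = 1)
#' q <- build_query(sp, "QM", size = 40, k = 0.25, seed = 2)
#' q$overlap_fraction  # 0.25
#' @export
build_query <- function(splits, mode = c("QO", "QNO", "QM", "QF"),
                        size, k = NULL, seed = 0L) {
  stopifnot(inherits(splits, "split_collection"))
  mode <- match.arg(mode)
  size <- as.integer(size)
  if (size < 1L) stop("query size must be positive")
  n_member <- switch(mode,
    QO = size, QF = size, QNO = 0L,
    QM = {
      if (is.null(k) || k < 0 || k > 1) stop("QM requires k in [0, 1]")
      as.integer(round_half_away(k * size))
    })
  n_non <- size - n_member
  if (n_member > n_samples(splits$train)) {
    stop("need ", n_member, " member samples but train holds ",
         n_samples(splits$train))
  }
  if (n_non > n_samples(splits$holdout)) {
    stop("need ", n_non, " non-member samples but the held-out pool holds ",
         n_samples(splits$holdout))
  }
  data <- with_seed(seed, {
    mem_idx <- if (n_member > 0L) sample.int(n_samples(splits$train), n_member) else integer(0)
    non_idx <- if (n_non > 0L) sample.int(n_samples(splits$holdout), n_non) else integer(0)
    parts <- list()
    if (n_member > 0L) parts$mem <- dataset_subset(splits$train, mem_idx)
    if (n_non > 0L) parts$non <- dataset_subset(splits$holdout, non_idx)
    combined <- if (length(parts) == 1L) parts[[1L]] else dataset_rbind(parts$mem, parts$non)
    dataset_subset(combined, sample.int(n_samples(combined)))
  })
  structure(list(data = data, mode = mode,
                 overlap_fraction = n_member / size,
                 size = size, seed = as.integer(seed)),
            class = "query_dataset")
}

# row-bind two labeled datasets (disjoint ids assumed/checked)
dataset_rbind <- function(a, b) {
  stopifnot(a$num_classes == b$num_classes)
  if (length(intersect(a$ids, b$ids)) > 0) stop("datasets share ids")
  shp <- attr(a$features, "shape")
  feats <- rbind(a$features, b$features)
  if (!is.null(shp)) attr(feats, "shape") <- shp
  labeled_dataset(feats, c(a$labels, b$labels), a$num_classes,
                  ids = c(a$ids, b$ids))
}

#' @export
print.query_dataset <- function(x, ...) {
  cat("<query_dataset>", x$mode, "| N =", x$size,
      "| overlap k =", format(x$overlap_fraction), "\n")
  invisible(x)
}

#' Fraction of a query overlapping a training set
#'
#' Returns `|query ids intersect train ids| / |query|`, the purity k of the
#' query dataset with respect to the given training data.
#'
#' @param query a [build_query()] result (or a `labeled_dataset`).
#' @param train the training [labeled_dataset()].
#' @return a fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(query, train) {
  ids <- if (inherits(query, "query_dataset")) query$data$ids else query$ids
  if (length(ids) == 0L) stop("empty query")
  length(intersect(ids, train$ids)) / length(ids)
}

#' Remove a forget set from a training set
#'
#' Returns the retain set: the training data minus the samples designated to
#' be forgotten. Every forget id must be a training id.
#'
#' @param train the training [labeled_dataset()].
#' @param forget a `query_dataset` (typically mode `"QF"`) or `labeled_dataset`.
#' @return a `labeled_dataset` with `n_samples(train) - n_samples(forget)` rows.
#' @export
retain_set <- function(train, forget) {
  ids <- if (inherits(forget, "query_dataset")) forget$data$ids else forget$ids
  missing <- setdiff(ids, train$ids)
  if (length(missing) > 0) {
    stop("forget ids not present in train: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  keep <- setdiff(train$ids, ids)
  if (length(keep) == 0L) {
    warning("forget set equals the training set; retain set is empty")
    return(structure(list(ids = character(0),
                          features = train$features[0, , drop = FALSE],
                          labels = integer(0), num_classes = train$num_classes),
                     class = "labeled_dataset"))
  }
  dataset_subset(train, keep)
}
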