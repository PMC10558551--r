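# Comparison methods: independent retraining at fraction k, SISA sharded
# unlearning, and the last-k-layers baselines CF-k (fine-tune) and EU-k
# (retrain from scratch), with the freezing contracts checkable by
# parameter-group fingerprints.

#' Train a model independently on a (fraction of a) training set
#'
#' Trains the architecture from scratch on a seeded `k`-fraction of
#' `train` minus `exclude`. `k = 1` with no exclusion is the "independent
#' teacher"; a smaller spec gives the "independent student".
#'
#' @param arch a [model_spec()].
#' @param train the training [labeled_dataset()].
#' @param k fraction of the (remaining) training data to use, in `(0, 1]`.
#' @param exclude optional `query_dataset` / `labeled_dataset` to remove
#'   before sampling (the data to be forgotten).
#' @param seed integer seed.
#' @param epochs,lr,batch_size optimisation settings.
#' @return a trained `afs_model`.
#' @export
train_independent <- function(arch, train, k = 1, exclude = NULL, seed = 0L,
                              epochs = 50L, lr = 0.01, batch_size = 32L) {
  stopifnot(inherits(arch, "model_spec"))
  base <- if (!is.null(exclude)) retain_set(train, exclude) else train
  n <- n_samples(base)
  take <- as.integer(round_half_away(k * n))
  if (take < 1L) stop("k-fraction of the training data is empty")
  sub <- if (take < n) {
    dataset_subset(base, with_seed(derive_seed(seed, 999L), sample.int(n, take)))
  } else base
  fit_classifier(arch, sub, epochs = epochs, lr = lr,
                 batch_size = batch_size, seed = seed)
}

# ---- SISA -------------------------------------------------------------------

#' SISA sharded training
#'
#' Partitions the training ids into `shards` shards by seeded uniform
#' assignment and trains one model per shard. Prediction aggregates the
#' per-shard models by majority vote over their arg-max classes
#' ([sisa_predict()]); unlearning retrains only affected shards
#' ([sisa_unlearn()]).
#'
#' @param arch a [model_spec()].
#' @param train the training [labeled_dataset()].
#' @param shards number of shards S (default 10).
#' @param seed integer seed (drives both the shard assignment and each
#'   shard model's training).
#' @param epochs,lr,batch_size per-shard optimisation settings.
#' @return an object of class `sisa_model` with the shard assignment
#'   (`shard_of`, named by sample id, values in `0..S-1`) and the S models.
#' @export
sisa_train <- function(arch, train, shards = 10L, seed = 0L,
                       epochs = 50L, lr = 0.01, batch_size = 32L) {
  stopifnot(inherits(arch, "model_spec"), inherits(train, "labeled_dataset"))
  shards <- as.integer(shards)
  n <- n_samples(train)
  if (shards < 2L || shards > n) stop("shards must be in 2..n")
  shard_of <- with_seed(derive_seed(seed, 777L),
                        sample(0:(shards - 1L), n, replace = TRUE))
  names(shard_of) <- train$ids
  models <- vector("list", shards)
  for (s in 0:(shards - 1L)) {
    ids <- train$ids[shard_of == s]
    if (length(ids) == 0L) next
    models[[s + 1L]] <- fit_classifier(arch, dataset_subset(train, ids),
                                       epochs = epochs, lr = lr,
                                       batch_size = batch_size,
                                       seed = derive_seed(seed, s))
  }
  structure(list(arch = arch, shards = shards, shard_of = shard_of,
                 models = models, train = train, seed = as.integer(seed),
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size)),
            class = "sisa_model")
}

#' @export
print.sisa_model <- function(x, ...) {
  cat("<sisa_model>", x$shards, "shards |", length(x$shard_of),
      "training samples |", x$arch$family, "\n")
  invisible(x)
}

#' Unlearn a forget set from a SISA model
#'
#' Retrains only the shards that contain forget ids, on those shards minus
#' the forget ids, with the same per-shard seeds; untouched shard models are
#' returned bitwise unchanged, so unlearning is idempotent for a fixed
#' forget set.
#'
#' @param model a [sisa_train()] result.
#' @param forget a `query_dataset` / `labeled_dataset`; every id must be
#'   mapped to a shard.
#' @return the updated `sisa_model`.
#' @export
sisa_unlearn <- function(model, forget) {
  stopifnot(inherits(model, "sisa_model"))
  ids <- if (inherits(forget, "query_dataset")) forget$data$ids else forget$ids
  unmapped <- setdiff(ids, names(model$shard_of))
  if (length(unmapped) > 0) {
    stop("forget ids not mapped to any shard: ",
         paste(utils::head(unmapped, 3), collapse = ", "))
  }
  affected <- sort(unique(model$shard_of[ids]))
  for (s in affected) {
    keep <- names(model$shard_of)[model$shard_of == s]
    keep <- setdiff(keep, ids)
    if (length(keep) == 0L) {
      warning("shard ", s, " is empty after removal; dropping its model")
      model$models[s + 1L] <- list(NULL)
      next
    }
    model$models[[s + 1L]] <- fit_classifier(model$arch,
                                             dataset_subset(model$train, keep),
                                             epochs = model$epochs, lr = model$lr,
                                             batch_size = model$batch_size,
                                             seed = derive_seed(model$seed, s))
  }
  model$shard_of <- model$shard_of[setdiff(names(model$shard_of), ids)]
  model
}

#' Aggregate SISA shard predictions
#'
#' Each shard model votes for its arg-max class; the aggregate probability of
#' class c is its vote share. Downstream arg-max tie-breaks resolve to the
#' lowest class index.
#'
#' @param model a `sisa_model`.
#' @param newdata feature matrix or [labeled_dataset()].
#' @return an n x C matrix of vote-share probabilities.
#' @export
sisa_predict <- function(model, newdata) {
  stopifnot(inherits(model, "sisa_model"))
  feats <- if (inherits(newdata, "labeled_dataset")) newdata$features else as.matrix(newdata)
  C <- model$arch$num_classes
  n <- nrow(feats)
  counts <- matrix(0, n, C)
  nvote <- 0L
  for (m in model$models) {
    if (is.null(m)) next
    cls <- predict(m, feats, type = "class")
    counts[cbind(seq_len(n), cls + 1L)] <- counts[cbind(seq_len(n), cls + 1L)] + 1
    nvote <- nvote + 1L
  }
  if (nvote == 0L) stop("no shard models available")
  counts / nvote
}

# SISA models expose the probabilistic-classifier contract through a light
# wrapper so that metric_matrix()/audit_dataset() accept them.
#' Wrap a SISA ensemble as a probabilistic classifier
#'
#' @param model a `sisa_model`.
#' @return an object usable wherever an `afs_model` is expected for
#'   prediction (class `sisa_classifier`).
#' @export
as_classifier <- function(model) {
  stopifnot(inherits(model, "sisa_model"))
  structure(list(sisa = model,
                 spec = list(num_classes = model$arch$num_classes,
                             is_image = model$arch$is_image,
                             input_shape = model$arch$input_shape,
                             family = "sisa")),
            class = c("sisa_classifier", "afs_model"))
}

#' @export
predict.sisa_classifier <- function(object, newdata, type = c("prob", "class", "logits"), ...) {
  type <- match.arg(type)
  p <- sisa_predict(object$sisa, newdata)
  switch(type, prob = p, class = row_argmax(p),
         logits = log(pmax(p, 1e-12)))
}

# ---- CF-k / EU-k ------------------------------------------------------------

# All-but-last-k parameterised layers of a sequential model.
frozen_indices <- function(model, k_layers) {
  idx <- param_layer_indices(model)
  depth <- length(idx)
  if (k_layers < 1L || k_layers > depth) {
    stop("k_layers must be in 1..", depth, " (model depth)")
  }
  idx[seq_len(depth - k_layers)]
}

#' Catastrophic-forgetting unlearning (CF-k)
#'
#' Fine-tunes the last `k_layers` parameterised layers of the model on the
#' retain set, starting from their current values, with all other layers
#' frozen (bitwise unchanged).
#'
#' @param model a trained sequential `afs_model` (mlp / small_cnn).
#' @param retain the retain [labeled_dataset()].
#' @param k_layers number of trailing layers to fine-tune (1..depth).
#' @param seed,epochs,lr,batch_size optimisation settings.
#' @return the fine-tuned `afs_model`.
#' @export
cf_k <- function(model, retain, k_layers, seed = 0L, epochs = 50L,
                 lr = 0.01, batch_size = 32L) {
  stopifnot(inherits(model, "afs_model"))
  if (is.null(model$layers)) stop("CF-k requires a trainable sequential model")
  frozen <- frozen_indices(model, k_layers)
  train_core(model, retain, epochs = epochs, lr = lr, batch_size = batch_size,
             seed = seed, frozen = frozen)$model
}

#' Exact-unlearning of the last k layers (EU-k)
#'
#' Like [cf_k()], but the last `k_layers` layers are first re-initialised
#' from `seed` (fresh He-scaled draws, as in [build_model()]) and then
#' retrained from scratch on the retain set; frozen layers are bitwise
#' unchanged. With `k_layers` equal to the model depth this coincides with
#' full retraining from scratch under the same seed.
#'
#' @inheritParams cf_k
#' @return the retrained `afs_model`.
#' @export
eu_k <- function(model, retain, k_layers, seed = 0L, epochs = 50L,
                 lr = 0.01, batch_size = 32L) {
  stopifnot(inherits(model, "afs_model"))
  if (is.null(model$layers)) stop("EU-k requires a trainable sequential model")
  frozen <- frozen_indices(model, k_layers)
  fresh <- build_model(model$spec, seed = seed)
  reinit <- setdiff(param_layer_indices(model), frozen)
  for (i in reinit) {
    model$layers[[i]]$W <- fresh$layers[[i]]$W
    if (!is.null(model$layers[[i]]$b)) model$layers[[i]]$b <- fresh$layers[[i]]$b
  }
  train_core(model, retain, epochs = epochs, lr = lr, batch_size = batch_size,
             seed = seed, frozen = frozen)$model
}
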