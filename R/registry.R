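#' Describe a classifier architecture
#'
#' A model spec names one of the registry families and fixes its shape so that
#' [build_model()] can instantiate it reproducibly. Four families are
#' supported: `"mlp"` (fully connected net over flat features), `"small_cnn"`
#' (two conv/pool stages and a dense head for single-channel images), and the
#' standard residual networks `"resnet18"` / `"resnet34"` (basic-block layer
#' plan, batch-norm, global average pooling; inference only).
#'
#' @param family one of `"mlp"`, `"small_cnn"`, `"resnet18"`, `"resnet34"`.
#' @param input_shape for `"mlp"`, the number of input features; for image
#'   families, an integer vector `c(H, W, C)` of height, width, channels.
#' @param num_classes number of classes C (output dimension).
#' @param hidden integer vector of hidden-layer widths (`"mlp"` only).
#' @param channels widths of the two convolutional stages (`"small_cnn"`).
#' @param dense_width width of the dense layer before the head (`"small_cnn"`).
#' @return an object of class `model_spec`.
#' @examples
#' model_spec("mlp", input_shape = 20, num_classes = 2, hidden = 32)
#' @export
model_spec <- function(family = c("mlp", "small_cnn", "resnet18", "resnet34"),
                       input_shape, num_classes,
                       hidden = 64L, channels = c(8L, 16L), dense_width = 32L) {
  family <- match.arg(family)
  num_classes <- as.integer(num_classes)
  if (num_classes < 2L) stop("`num_classes` must be at least 2")
  is_image <- family != "mlp"
  input_shape <- as.integer(input_shape)
  if (family == "mlp") {
    input_shape <- prod(input_shape)
  } else if (family == "small_cnn") {
    if (length(input_shape) == 1L) {
      side <- as.integer(round(sqrt(input_shape)))
      if (side * side != input_shape) stop("cannot infer a square image side from input_shape")
      input_shape <- c(side, side, 1L)
    }
    if (length(input_shape) != 3L) stop("image input_shape must be c(H, W, C)")
  } else {
    if (length(input_shape) != 3L) input_shape <- c(224L, 224L, 3L)
  }
  structure(list(family = family, input_shape = input_shape,
                 num_classes = num_classes, hidden = as.integer(hidden),
                 channels = as.integer(channels),
                 dense_width = as.integer(dense_width),
                 is_image = is_image),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$family,
      "| input:", paste(x$input_shape, collapse = "x"),
      "| classes:", x$num_classes, "\n")
  invisible(x)
}

resnet_blocks <- function(family) {
  switch(family, resnet18 = c(2L, 2L, 2L, 2L), resnet34 = c(3L, 4L, 6L, 3L),
         stop("not a resnet family"))
}

build_basic_block <- function(c_in, c_out, stride) {
  blk <- list(conv1 = layer_conv(c_in, c_out, 3L, stride, 1L, bias = FALSE),
              bn1 = layer_batchnorm(c_out),
              conv2 = layer_conv(c_out, c_out, 3L, 1L, 1L, bias = FALSE),
              bn2 = layer_batchnorm(c_out))
  if (stride != 1L || c_in != c_out) {
    blk$down_conv <- layer_conv(c_in, c_out, 1L, stride, 0L, bias = FALSE)
    blk$down_bn <- layer_batchnorm(c_out)
  }
  blk
}

#' Instantiate a classifier from a spec
#'
#' Parameters are initialised with He-scaled Gaussian draws under `seed`, so
#' the same `(spec, seed)` pair always yields a bitwise-identical model
#' ([model_fingerprint()] is stable). MLP and small-CNN models are trainable;
#' the residual networks are built for inference and parameter accounting.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed controlling initialisation.
#' @return an object of class `afs_model`.
#' @examples
#' m <- build_model(model_spec("mlp", 20, 2, hidden = 32), seed = 1)
#' count_parameters(m)  # 20*32 + 32 + 32*2 + 2 = 738
#' @export
build_model <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "model_spec"))
  with_seed(seed, {
    model <- list(spec = spec, seed = as.integer(seed))
    if (spec$family == "mlp") {
      dims <- c(spec$input_shape, spec$hidden, spec$num_classes)
      layers <- list()
      for (i in seq_len(length(dims) - 1L)) {
        layers[[length(layers) + 1L]] <- layer_dense(dims[i], dims[i + 1L])
        if (i < length(dims) - 1L) layers[[length(layers) + 1L]] <- layer_relu()
      }
      model$layers <- layers
    } else if (spec$family == "small_cnn") {
      hw <- spec$input_shape
      ch <- spec$channels
      flat <- (hw[1] %/% 4L) * (hw[2] %/% 4L) * ch[2]
      model$layers <- list(
        layer_conv(hw[3], ch[1], 3L, 1L, 1L), layer_relu(), layer_maxpool(2L),
        layer_conv(ch[1], ch[2], 3L, 1L, 1L), layer_relu(), layer_maxpool(2L),
        layer_flatten(),
        layer_dense(flat, spec$dense_width), layer_relu(),
        layer_dense(spec$dense_width, spec$num_classes))
    } else {
      nblk <- resnet_blocks(spec$family)
      widths <- c(64L, 128L, 256L, 512L)
      net <- list(conv1 = layer_conv(spec$input_shape[3], 64L, 7L, 2L, 3L, bias = FALSE),
                  bn1 = layer_batchnorm(64L))
      stages <- vector("list", 4L)
      c_in <- 64L
      for (s in 1:4) {
        blocks <- vector("list", nblk[s])
        for (b in seq_len(nblk[s])) {
          stride <- if (s > 1L && b == 1L) 2L else 1L
          blocks[[b]] <- build_basic_block(c_in, widths[s], stride)
          c_in <- widths[s]
        }
        stages[[s]] <- blocks
      }
      net$stages <- stages
      net$fc <- layer_dense(512L, spec$num_classes)
      model$resnet <- net
    }
    class(model) <- "afs_model"
    model
  })
}

#' @export
print.afs_model <- function(x, ...) {
  cat("<afs_model>", x$spec$family,
      "| classes:", x$spec$num_classes,
      "| parameters:", format(count_parameters(x), big.mark = ","),
      "\n  fingerprint:", substr(model_fingerprint(x), 1, 12), "\n")
  invisible(x)
}

# ---- parameter accounting ---------------------------------------------------

param_fields <- c("W", "b", "gamma", "beta")

collect_params <- function(x) {
  out <- list()
  walk <- function(node, prefix) {
    if (!is.list(node)) return()
    nm <- names(node)
    for (field in param_fields) {
      if (field %in% nm && is.numeric(node[[field]])) {
        out[[paste0(prefix, ".", field)]] <<- node[[field]]
      }
    }
    for (i in seq_along(node)) {
      child <- node[[i]]
      if (is.list(child)) {
        tag <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
        walk(child, paste0(prefix, ".", tag))
      }
    }
  }
  if (!is.null(x$layers)) walk(x$layers, "seq")
  if (!is.null(x$resnet)) walk(x$resnet, "res")
  out
}

#' Count trainable parameters
#'
#' Sums the element counts of every weight, bias and batch-norm scale/shift in
#' the model (batch-norm running statistics are not parameters and are not
#' counted), matching the usual deep-learning convention.
#'
#' @param model an `afs_model` or a `model_spec` (which is instantiated first).
#' @return a positive integer count.
#' @examples
#' count_parameters(model_spec("mlp", 20, 2, hidden = 32))
#' @export
count_parameters <- function(model) {
  if (inherits(model, "model_spec")) model <- build_model(model, seed = 0L)
  stopifnot(inherits(model, "afs_model"))
  sum(vapply(collect_params(model), length, numeric(1)))
}

#' Stable content fingerprint of a model's parameters
#'
#' Two models have equal fingerprints iff every parameter array is bitwise
#' identical; used throughout to assert seeded determinism and layer freezing.
#'
#' @param model an `afs_model`.
#' @return a 32-character md5 string.
#' @export
model_fingerprint <- function(model) {
  content_hash(collect_params(model))
}

# Fingerprint of each parameterised layer of a sequential model, in order.
layer_fingerprints <- function(model) {
  idx <- param_layer_indices(model)
  vapply(idx, function(i) {
    ly <- model$layers[[i]]
    content_hash(list(ly$W, ly$b))
  }, character(1))
}

# ---- prediction -------------------------------------------------------------

resnet_forward <- function(model, x) {
  net <- model$resnet
  cur <- as_image_batch(x, model$spec$input_shape)
  cur <- conv_forward(net$conv1, cur)$y
  cur <- batchnorm_forward(net$bn1, cur)
  cur <- pmax(cur, 0)
  cur <- maxpool_forward(layer_maxpool(3L, 2L, 1L), cur)$y
  for (stage in net$stages) {
    for (blk in stage) {
      idty <- cur
      out <- conv_forward(blk$conv1, cur)$y
      out <- pmax(batchnorm_forward(blk$bn1, out), 0)
      out <- conv_forward(blk$conv2, out)$y
      out <- batchnorm_forward(blk$bn2, out)
      if (!is.null(blk$down_conv)) {
        idty <- batchnorm_forward(blk$down_bn, conv_forward(blk$down_conv, cur)$y)
      }
      cur <- pmax(out + idty, 0)
    }
  }
  d <- dim(cur)
  # global average pool: (H*W) x (C*N) column means, then samples as rows
  pooled <- t(matrix(colMeans(matrix(cur, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
  sweep(pooled %*% net$fc$W, 2L, net$fc$b, "+")
}

model_logits <- function(model, features) {
  features <- as.matrix(features)
  if (!is.null(model$resnet)) return(resnet_forward(model, features))
  nn_forward(model, features)$logits
}

#' Predict class probabilities, classes or logits
#'
#' Inference is deterministic: the same features and the same model
#' fingerprint always produce identical output. Rows of the probability
#' matrix are non-negative and sum to one.
#'
#' @param object an `afs_model`.
#' @param newdata a [labeled_dataset()] or a numeric feature matrix
#'   (one row per sample).
#' @param type `"prob"` for an n x C probability matrix (softmax of the
#'   logits), `"class"` for 0-based predicted labels (lowest index wins ties),
#'   `"logits"` for the raw pre-softmax scores.
#' @param ... unused.
#' @return matrix or integer vector according to `type`.
#' @export
predict.afs_model <- function(object, newdata, type = c("prob", "class", "logits"), ...) {
  type <- match.arg(type)
  features <- if (inherits(newdata, "labeled_dataset")) newdata$features else newdata
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  expected <- if (object$spec$is_image) prod(object$spec$input_shape) else object$spec$input_shape
  if (ncol(features) != expected) {
    stop("feature width ", ncol(features), " does not match model input size ", expected)
  }
  logits <- model_logits(object, features)
  switch(type,
         logits = logits,
         prob = softmax(logits),
         class = row_argmax(softmax(logits)))
}

#' Probabilistic-classifier interface
#'
#' `predict_proba()` is a convenience wrapper equal to
#' `predict(model, newdata, type = "prob")`.
#'
#' @inheritParams predict.afs_model
#' @param model an `afs_model`.
#' @return an n x C matrix of class probabilities.
#' @export
predict_proba <- function(model, newdata) predict(model, newdata, type = "prob")

# accuracy of a model on a labeled dataset
model_accuracy <- function(model, data) {
  mean(predict(model, data, type = "class") == data$labels)
}
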