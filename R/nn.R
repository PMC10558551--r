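# Minimal neural-network engine: sequential nets (dense / relu / conv /
# maxpool / flatten) with exact backpropagation and an Adam optimizer, plus
# inference-mode batch normalisation for the residual-network family.
#
# Conventions:
#   * tabular activations are n x d matrices (one row per sample);
#   * image activations are (H, W, C, N) arrays;
#   * labels are 0-based integers; logits/probabilities are n x C matrices.

# ---- layer constructors -----------------------------------------------------

layer_dense <- function(d_in, d_out) {
  list(type = "dense",
       W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

layer_relu <- function() list(type = "relu")

layer_conv <- function(c_in, c_out, kernel, stride = 1L, pad = 0L, bias = TRUE) {
  fan_in <- kernel * kernel * c_in
  list(type = "conv",
       W = matrix(stats::rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)), fan_in, c_out),
       b = if (bias) numeric(c_out) else NULL,
       c_in = c_in, c_out = c_out, kernel = as.integer(kernel),
       stride = as.integer(stride), pad = as.integer(pad))
}

layer_maxpool <- function(size, stride = size, pad = 0L) {
  list(type = "maxpool", size = as.integer(size),
       stride = as.integer(stride), pad = as.integer(pad))
}

layer_flatten <- function() list(type = "flatten")

layer_batchnorm <- function(channels, eps = 1e-5) {
  list(type = "batchnorm", gamma = rep(1, channels), beta = numeric(channels),
       mean = numeric(channels), var = rep(1, channels), eps = eps)
}

# ---- im2col machinery -------------------------------------------------------

# Linear gather indices turning a padded (Hp, Wp, C, N) array into a
# (k*k*C) x (oh*ow*N) patch matrix.
im2col_index <- function(Hp, Wp, C, N, kernel, stride, oh, ow) {
  k <- kernel
  # offsets within one patch, one channel plane at a time
  dr <- rep.int(seq_len(k), k)                       # row offset within patch
  dc <- rep(seq_len(k), each = k)                    # col offset within patch
  base_patch <- dr + (dc - 1L) * Hp                  # length k*k
  chan_off <- (seq_len(C) - 1L) * (Hp * Wp)
  patch_rows <- as.vector(outer(base_patch, chan_off, "+"))  # k*k*C
  # top-left corner of every output position
  or_ <- (rep.int(seq_len(oh), ow) - 1L) * stride
  oc_ <- (rep(seq_len(ow), each = oh) - 1L) * stride
  corners <- or_ + oc_ * Hp                          # oh*ow, 0-based linear
  samp_off <- (seq_len(N) - 1L) * (Hp * Wp * C)
  cols <- as.vector(outer(corners, samp_off, "+"))   # oh*ow*N
  outer(patch_rows, cols, "+")                       # matrix of linear indices
}

pad_input <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

conv_forward <- function(layer, x) {
  d <- dim(x)  # H, W, C, N
  stopifnot(d[3] == layer$c_in)
  k <- layer$kernel; s <- layer$stride; p <- layer$pad
  oh <- (d[1] + 2L * p - k) %/% s + 1L
  ow <- (d[2] + 2L * p - k) %/% s + 1L
  xp <- pad_input(x, p)
  idx <- im2col_index(dim(xp)[1], dim(xp)[2], d[3], d[4], k, s, oh, ow)
  cols <- matrix(xp[idx], nrow = nrow(idx))
  out <- crossprod(layer$W, cols)                    # c_out x (oh*ow*N)
  if (!is.null(layer$b)) out <- out + layer$b
  y <- aperm(array(out, c(layer$c_out, oh, ow, d[4])), c(2, 3, 1, 4))
  list(y = y, cols = cols, idx = idx, in_dim = d, padded_dim = dim(xp),
       out_hw = c(oh, ow))
}

conv_backward <- function(layer, cache, dy) {
  d <- cache$in_dim
  dy_mat <- matrix(aperm(dy, c(3, 1, 2, 4)), nrow = layer$c_out)
  dW <- cols_tcrossprod(cache$cols, dy_mat)
  db <- if (!is.null(layer$b)) rowSums(dy_mat) else NULL
  dcols <- layer$W %*% dy_mat                        # (k*k*C) x (oh*ow*N)
  # scatter-add into the padded input
  agg <- rowsum(as.vector(dcols), group = as.vector(cache$idx))
  dxp <- numeric(prod(cache$padded_dim))
  dxp[as.integer(rownames(agg))] <- agg
  dxp <- array(dxp, cache$padded_dim)
  p <- layer$pad
  dx <- if (p > 0L) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE] else dxp
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

cols_tcrossprod <- function(cols, dy_mat) tcrossprod(cols, dy_mat)

maxpool_forward <- function(layer, x) {
  d <- dim(x)  # H, W, C, N
  # fold channels into the batch so pooling is per-channel
  xf <- array(x, c(d[1], d[2], 1L, d[3] * d[4]))
  k <- layer$size; s <- layer$stride; p <- layer$pad
  oh <- (d[1] + 2L * p - k) %/% s + 1L
  ow <- (d[2] + 2L * p - k) %/% s + 1L
  xp <- pad_input(xf, p)
  idx <- im2col_index(dim(xp)[1], dim(xp)[2], 1L, d[3] * d[4], k, s, oh, ow)
  patch <- matrix(xp[idx], nrow = nrow(idx))
  which_max <- max.col(t(patch), ties.method = "first")
  vals <- patch[cbind(which_max, seq_len(ncol(patch)))]
  y <- array(vals, c(oh, ow, d[3], d[4]))
  list(y = y, idx = idx, which_max = which_max, in_dim = d,
       padded_dim = dim(xp))
}

maxpool_backward <- function(layer, cache, dy) {
  d <- cache$in_dim
  winners <- cache$idx[cbind(cache$which_max, seq_len(ncol(cache$idx)))]
  agg <- rowsum(as.vector(dy), group = winners)
  dxp <- numeric(prod(cache$padded_dim))
  dxp[as.integer(rownames(agg))] <- agg
  dxp <- array(dxp, cache$padded_dim)
  p <- layer$pad
  dx <- if (p > 0L) dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE] else dxp
  array(dx, d)
}

batchnorm_forward <- function(layer, x) {
  # inference-mode normalisation over the channel axis of (H, W, C, N)
  scale <- layer$gamma / sqrt(layer$var + layer$eps)
  shift <- layer$beta - layer$mean * scale
  d <- dim(x)
  sweep(sweep(x, 3L, scale, "*"), 3L, shift, "+")
}

# ---- sequential forward / backward -----------------------------------------

# x: n x d feature matrix; image nets reshape according to input_shape (H,W,C).
as_image_batch <- function(x, input_shape) {
  n <- nrow(x)
  a <- array(t(x), c(input_shape[1], input_shape[2], input_shape[3], n))
  a
}

as_feature_matrix <- function(a) {
  d <- dim(a)
  t(matrix(a, d[1] * d[2] * d[3], d[4]))
}

nn_forward <- function(model, x, keep_cache = FALSE) {
  layers <- model$layers
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  cur <- x
  if (model$spec$is_image) cur <- as_image_batch(x, model$spec$input_shape)
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "dense") {
      if (keep_cache) caches[[i]] <- list(x = cur)
      cur <- sweep(cur %*% ly$W, 2L, ly$b, "+")
    } else if (ly$type == "relu") {
      if (keep_cache) caches[[i]] <- list(mask = cur > 0)
      cur <- pmax(cur, 0)
    } else if (ly$type == "conv") {
      fw <- conv_forward(ly, cur)
      if (keep_cache) caches[[i]] <- fw
      cur <- fw$y
    } else if (ly$type == "maxpool") {
      fw <- maxpool_forward(ly, cur)
      if (keep_cache) caches[[i]] <- fw
      cur <- fw$y
    } else if (ly$type == "flatten") {
      if (keep_cache) caches[[i]] <- list(in_dim = dim(cur))
      cur <- as_feature_matrix(cur)
    } else if (ly$type == "batchnorm") {
      cur <- batchnorm_forward(ly, cur)
    } else stop("unknown layer type: ", ly$type)
  }
  list(logits = cur, caches = caches)
}

# dlogits: gradient of the scalar loss w.r.t. the logits.
nn_backward <- function(model, caches, dlogits) {
  layers <- model$layers
  grads <- vector("list", length(layers))
  dcur <- dlogits
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$type == "dense") {
      x <- caches[[i]]$x
      grads[[i]] <- list(W = crossprod(x, dcur), b = colSums(dcur))
      dcur <- tcrossprod(dcur, ly$W)
    } else if (ly$type == "relu") {
      dcur <- dcur * caches[[i]]$mask
    } else if (ly$type == "conv") {
      bw <- conv_backward(ly, caches[[i]], dcur)
      grads[[i]] <- list(W = bw$dW, b = bw$db)
      dcur <- bw$dx
    } else if (ly$type == "maxpool") {
      dcur <- maxpool_backward(ly, caches[[i]], dcur)
    } else if (ly$type == "flatten") {
      dcur <- array(t(dcur), caches[[i]]$in_dim)
    } else stop("backward not supported for layer type: ", ly$type)
  }
  grads
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(model) {
  st <- lapply(model$layers, function(ly) {
    if (is.null(ly$W)) return(NULL)
    s <- list(mW = ly$W * 0, vW = ly$W * 0)
    if (!is.null(ly$b)) { s$mb <- ly$b * 0; s$vb <- ly$b * 0 }
    s
  })
  list(state = st, t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(model, opt, grads, lr, frozen = integer(0)) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g) || i %in% frozen) next
    s <- opt$state[[i]]
    s$mW <- b1 * s$mW + (1 - b1) * g$W
    s$vW <- b2 * s$vW + (1 - b2) * g$W^2
    model$layers[[i]]$W <- model$layers[[i]]$W -
      lr * (s$mW / c1) / (sqrt(s$vW / c2) + opt$eps)
    if (!is.null(g$b)) {
      s$mb <- b1 * s$mb + (1 - b1) * g$b
      s$vb <- b2 * s$vb + (1 - b2) * g$b^2
      model$layers[[i]]$b <- model$layers[[i]]$b -
        lr * (s$mb / c1) / (sqrt(s$vb / c2) + opt$eps)
    }
    opt$state[[i]] <- s
  }
  list(model = model, opt = opt)
}

# indices of layers that carry parameters, in network order
param_layer_indices <- function(model) {
  which(vapply(model$layers, function(ly) !is.null(ly$W), logical(1)))
}

# ---- loss gradients at the logits ------------------------------------------

# cross-entropy on hard labels; returns loss and d(loss)/d(logits)
ce_loss_grad <- function(logits, y) {
  n <- nrow(logits)
  p <- softmax(logits)
  picked <- p[cbind(seq_len(n), y + 1L)]
  loss <- -mean(log(pmax(picked, 1e-300)))
  g <- p
  g[cbind(seq_len(n), y + 1L)] <- g[cbind(seq_len(n), y + 1L)] - 1
  list(loss = loss, grad = g / n)
}

# temperature-T distillation: T^2 * mean KL(teacher_T || student_T)
kd_loss_grad <- function(student_logits, teacher_logits, temperature) {
  n <- nrow(student_logits)
  ps <- softmax(student_logits / temperature)
  pt <- softmax(teacher_logits / temperature)
  loss <- kd_loss(ps, pt, temperature)
  grad <- temperature * (ps - pt) / n
  list(loss = loss, grad = grad)
}

# uniformity-pushing forget term: mean(log C - H(p)); gradient wrt logits
forget_loss_grad <- function(logits) {
  n <- nrow(logits)
  p <- softmax(logits)
  H <- row_entropy(p)
  loss <- mean(log(ncol(p)) - H)
  lp <- ifelse(p > 0, log(p), 0)
  grad <- p * (lp + H) / n
  list(loss = loss, grad = grad)
}
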