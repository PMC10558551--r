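# Shared seeded training loop. One primitive serves plain supervised
# training, knowledge distillation, and the audit-guided forgetting loop, so
# that the reduction contracts (beta = 0 and/or kd_weight = 0 collapse to the
# simpler objective with an identical trajectory) hold by construction.

# Per-batch gradient of
#   (1 - kd_weight) * CE(hard labels) + kd_weight * KD(teacher, T)
# plus, on a separate forget minibatch, beta * (log C - mean entropy).
# Batch order depends only on (seed, epoch); the forget stream draws from an
# independent derived seed so its presence never perturbs the retain batches.
train_core <- function(model, data, epochs, lr, batch_size, seed,
                       teacher = NULL, kd_weight = 0, temperature = 1,
                       forget_features = NULL, beta = 0,
                       frozen = integer(0), epoch_hook = NULL) {
  stopifnot(inherits(model, "afs_model"))
  n <- n_samples(data)
  if (n == 0L) stop("cannot train on an empty dataset")
  X <- data$features
  y <- data$labels
  opt <- adam_init(model)
  use_forget <- !is.null(forget_features) && nrow(forget_features) > 0L
  nf <- if (use_forget) nrow(forget_features) else 0L
  fbatch <- if (use_forget) min(batch_size, nf) else 0L
  history <- list()
  stop_reason <- NA_character_
  teacher_logits_all <- NULL
  if (!is.null(teacher) && kd_weight > 0) {
    teacher_logits_all <- predict(teacher, X, type = "logits")
  }
  for (epoch in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, epoch), sample.int(n))
    ford <- if (use_forget) with_seed(derive_seed(seed, 100000L + epoch), sample.int(nf)) else NULL
    fpos <- 0L
    sums <- c(hard = 0, kd = 0, forget = 0); nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      fw <- nn_forward(model, X[idx, , drop = FALSE], keep_cache = TRUE)
      hard <- ce_loss_grad(fw$logits, y[idx])
      gl <- (1 - kd_weight) * hard$grad
      kd_val <- 0
      if (!is.null(teacher_logits_all) && kd_weight > 0) {
        kd <- kd_loss_grad(fw$logits, teacher_logits_all[idx, , drop = FALSE], temperature)
        gl <- gl + kd_weight * kd$grad
        kd_val <- kd$loss
      }
      grads <- nn_backward(model, fw$caches, gl)
      forget_val <- 0
      if (use_forget && beta > 0) {
        # cycle through a per-epoch shuffled order of the forget set
        take <- ((fpos + seq_len(fbatch) - 1L) %% nf) + 1L
        fpos <- (fpos + fbatch) %% nf
        fidx <- ford[take]
        ffw <- nn_forward(model, forget_features[fidx, , drop = FALSE], keep_cache = TRUE)
        fl <- forget_loss_grad(ffw$logits)
        fgrads <- nn_backward(model, ffw$caches, beta * fl$grad)
        for (li in seq_along(grads)) {
          if (is.null(grads[[li]])) next
          grads[[li]]$W <- grads[[li]]$W + fgrads[[li]]$W
          if (!is.null(grads[[li]]$b)) grads[[li]]$b <- grads[[li]]$b + fgrads[[li]]$b
        }
        forget_val <- fl$loss
      }
      st <- adam_step(model, opt, grads, lr, frozen = frozen)
      model <- st$model; opt <- st$opt
      sums <- sums + c(hard$loss, kd_val, forget_val); nb <- nb + 1L
    }
    stats <- as.list(sums / nb)
    stats$epoch <- epoch
    stats$beta <- beta
    if (!is.null(epoch_hook)) {
      hk <- epoch_hook(model, epoch, stats)
      if (!is.null(hk$stats)) stats <- hk$stats
      if (!is.null(hk$beta)) beta <- hk$beta
      history[[epoch]] <- stats
      if (isTRUE(hk$stop)) { stop_reason <- hk$reason %||% "early_stop"; break }
    } else {
      history[[epoch]] <- stats
    }
  }
  hist_df <- do.call(rbind, lapply(history, function(s) as.data.frame(s[order(names(s))])))
  list(model = model, history = hist_df, stop_reason = stop_reason)
}

# Supervised fit of a fresh model from a spec (hard labels only).
fit_classifier <- function(spec, data, epochs = 50L, lr = 0.01,
                           batch_size = 32L, seed = 0L, frozen = integer(0)) {
  model <- build_model(spec, seed = seed)
  if (epochs == 0L) return(model)
  train_core(model, data, epochs = epochs, lr = lr, batch_size = batch_size,
             seed = seed)$model
}
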