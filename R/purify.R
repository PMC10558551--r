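# Knowledge purification: teacher-student transfer whose objective carries an
# audit-driven forget term. The dataset-level audit p-value is piecewise
# constant in the model parameters and therefore has no gradient; the forget
# pressure is realised as a differentiable uniformity-pushing surrogate on
# the forget set, and the audit acts through a negative-feedback schedule on
# its weight beta: while the forget set still audits as member-like
# (p > target_p) beta grows, once it audits as forgotten beta decays.

#' Knowledge-distillation loss
#'
#' Temperature-scaled distillation divergence
#' `T^2 * mean_i KL(teacher_i || student_i)` over rows of
#' temperature-softened probabilities. Zero iff the rows coincide.
#'
#' @param student_probs_T,teacher_probs_T matrices of temperature-`T`
#'   softened class probabilities (same shape).
#' @param temperature the softening temperature T > 0.
#' @return a non-negative scalar.
#' @examples
#' p <- matrix(c(0.5, 0.5), 1)
#' kd_loss(p, matrix(c(1, 0), 1), temperature = 1)  # log(2)
#' @export
kd_loss <- function(student_probs_T, teacher_probs_T, temperature = 1) {
  s <- as.matrix(student_probs_T); t_ <- as.matrix(teacher_probs_T)
  if (!all(dim(s) == dim(t_))) stop("student and teacher probability shapes differ")
  if (temperature <= 0) stop("temperature must be positive")
  lt <- ifelse(t_ > 0, log(t_), 0)
  ls <- ifelse(t_ > 0, log(pmax(s, 1e-300)), 0)  # terms with t = 0 vanish
  kl <- rowSums(t_ * (lt - ls))
  temperature^2 * mean(kl)
}

#' Forget loss (uniformity pressure on the forget set)
#'
#' `mean(log C - H(p))` over the batch: zero iff every prediction is uniform,
#' maximal (`log C`) iff every prediction is one-hot. Minimising it drives
#' the student's predictions on the forget set towards ignorance.
#'
#' @param probs matrix of class-probability rows on a forget-set batch.
#' @return a value in `[0, log C]`.
#' @examples
#' forget_loss(matrix(rep(0.25, 4), 1))  # 0
#' @export
forget_loss <- function(probs) {
  probs <- as.matrix(probs)
  if (nrow(probs) == 0L) stop("empty forget batch")
  mean(log(ncol(probs)) - row_entropy(probs))
}

#' Total knowledge-purification loss
#'
#' `(1 - kd_weight) * hard + kd_weight * kd + beta * forget`. With
#' `beta = 0, kd_weight = 0` it reduces to plain supervised training, with
#' `beta = 0` to standard knowledge distillation.
#'
#' @param hard,kd,forget the component losses.
#' @param kd_weight distillation mixing weight in `[0, 1]`.
#' @param beta forget-term weight `>= 0`.
#' @return the scalar objective.
#' @export
total_loss <- function(hard, kd, forget, kd_weight, beta) {
  (1 - kd_weight) * hard + kd_weight * kd + beta * forget
}

#' Configuration for audit-guided forgetting
#'
#' Houses the knowledge-purification hyperparameters. `epochs = 50` follows
#' the training protocol of the audit/forgetting study; the learning rate
#' default (Adam, 1e-2) is sized for the desk-scale synthetic fixtures this
#' package trains end-to-end. None of the loss weights are prescribed by the
#' protocol; the defaults here are the package's own and are all tunable.
#'
#' @param kd_weight distillation weight `[0, 1]` balancing hard-label loss
#'   against distillation loss.
#' @param temperature soft-target temperature T > 0.
#' @param beta_init initial forget-term weight (also its feedback floor).
#' @param beta_multiplier multiplicative feedback step: beta grows by this
#'   factor while the forget set still audits member-like, and shrinks by it
#'   once forgotten.
#' @param beta_cap upper bound on beta.
#' @param target_p audit p-value on the forget set at or below which
#'   forgetting is deemed achieved.
#' @param patience consecutive achieved epochs required before early stop.
#' @param acc_budget maximum tolerated drop of retained-test accuracy below
#'   the teacher's before early stop is allowed.
#' @param k retained fraction of the retain set used for transfer
#'   (protocol values: 0.25, 0.5, 0.75).
#' @param epochs,lr,batch_size optimisation settings (Adam).
#' @param calibration_epochs shadow-model training epochs for the in-loop audit.
#' @param seed integer seed.
#' @return an object of class `forget_config`.
#' @export
forget_config <- function(kd_weight = 0.5, temperature = 2, beta_init = 1,
                          beta_multiplier = 2, beta_cap = 64, target_p = 0.05,
                          patience = 3L, acc_budget = 0.05, k = 0.5,
                          epochs = 50L, lr = 0.01, batch_size = 32L,
                          calibration_epochs = 50L, seed = 0L) {
  if (kd_weight < 0 || kd_weight > 1) stop("kd_weight must be in [0, 1]")
  if (temperature <= 0) stop("temperature must be positive")
  if (beta_init < 0) stop("beta_init must be >= 0")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (k <= 0 || k > 1) stop("k must be in (0, 1]")
  structure(list(kd_weight = kd_weight, temperature = temperature,
                 beta_init = beta_init, beta_multiplier = beta_multiplier,
                 beta_cap = beta_cap, target_p = target_p,
                 patience = as.integer(patience), acc_budget = acc_budget,
                 k = k, epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 calibration_epochs = as.integer(calibration_epochs),
                 seed = as.integer(seed)),
            class = "forget_config")
}

#' @export
print.forget_config <- function(x, ...) {
  cat("<forget_config> kd_weight =", x$kd_weight, "| T =", x$temperature,
      "| beta:", x$beta_init, "x", x$beta_multiplier, "cap", x$beta_cap,
      "\n  target_p =", x$target_p, "| k =", x$k, "| epochs =", x$epochs,
      "| lr =", x$lr, "\n")
  invisible(x)
}

#' Audit-guided forgetting (knowledge purification)
#'
#' Trains a student model from a pre-trained teacher on a seeded `k`-fraction
#' of the retain set (training data minus the forget set) with the combined
#' objective [total_loss()]. After every epoch the forget set is audited on
#' the current student against thresholds calibrated once up front (shadow
#' model of the student architecture, frozen across epochs), and the forget
#' weight beta is updated in negative feedback: multiplied while
#' `p > target_p` (capped), divided once the forget set audits as forgotten
#' (floored at `beta_init`). Training stops early when `p <= target_p` for
#' `patience` consecutive epochs and, if a test set is supplied, the
#' student's test accuracy is within `acc_budget` of the teacher's.
#'
#' @param teacher the pre-trained teacher `afs_model` (trained on `train`).
#' @param student_spec [model_spec()] of the (smaller) student.
#' @param train the full training [labeled_dataset()] of the teacher.
#' @param forget a `query_dataset` (mode `"QF"`) or `labeled_dataset` whose
#'   ids all lie in `train`.
#' @param calibration calibration [labeled_dataset()] disjoint from `train`.
#' @param config a [forget_config()].
#' @param test optional held-out [labeled_dataset()] for the accuracy trace
#'   and the early-stop utility condition.
#' @return an object of class `afs_kp`: `student` (the trained model),
#'   `trace` (one row per completed epoch: losses, beta, forget-set p-value,
#'   test accuracy), `thresholds`, `config`, `stop_reason`.
#' @export
afs_train <- function(teacher, student_spec, train, forget, calibration,
                      config = forget_config(), test = NULL) {
  stopifnot(inherits(teacher, "afs_model"), inherits(student_spec, "model_spec"))
  if (teacher$spec$num_classes != student_spec$num_classes) {
    stop("teacher and student disagree on the class count")
  }
  fdata <- if (inherits(forget, "query_dataset")) forget$data else forget
  has_forget <- !is.null(fdata) && n_samples(fdata) > 0L
  retain <- if (has_forget) retain_set(train, fdata) else train
  nr <- n_samples(retain)
  take <- as.integer(round_half_away(config$k * nr))
  if (take < 1L) stop("k-fraction of the retain set is empty")
  sub <- if (take < nr) {
    dataset_subset(retain, with_seed(derive_seed(config$seed, 999L), sample.int(nr, take)))
  } else retain
  thresholds <- NULL
  teacher_test_acc <- if (!is.null(test)) model_accuracy(teacher, test) else NA_real_
  if (has_forget) {
    thresholds <- calibrate(student_spec, calibration,
                            epochs = config$calibration_epochs, lr = config$lr,
                            batch_size = config$batch_size,
                            seed = derive_seed(config$seed, 555L))
  }
  student <- build_model(student_spec, seed = config$seed)
  consecutive <- 0L
  hook <- function(model, epoch, stats) {
    p <- NA_real_
    if (has_forget) {
      mm <- metric_matrix(model, fdata)
      p <- audit_pvalue(membership_votes(mm, thresholds)$vote)
    }
    acc <- if (!is.null(test)) model_accuracy(model, test) else NA_real_
    stats$p_forget <- p
    stats$test_accuracy <- acc
    new_beta <- stats$beta
    stop <- FALSE; reason <- NULL
    if (has_forget && config$beta_init > 0) {
      if (p > config$target_p) {
        new_beta <- min(stats$beta * config$beta_multiplier, config$beta_cap)
        consecutive <<- 0L
      } else {
        new_beta <- max(stats$beta / config$beta_multiplier, config$beta_init)
        consecutive <<- consecutive + 1L
        acc_ok <- is.na(teacher_test_acc) || (acc >= teacher_test_acc - config$acc_budget)
        if (consecutive >= config$patience && acc_ok) {
          stop <- TRUE; reason <- "forgotten_within_budget"
        }
      }
    }
    list(stats = stats, beta = new_beta, stop = stop, reason = reason)
  }
  fit <- train_core(student, sub,
                    epochs = config$epochs, lr = config$lr,
                    batch_size = config$batch_size, seed = config$seed,
                    teacher = teacher, kd_weight = config$kd_weight,
                    temperature = config$temperature,
                    forget_features = if (has_forget) fdata$features else NULL,
                    beta = if (has_forget) config$beta_init else 0,
                    epoch_hook = hook)
  structure(list(student = fit$model, trace = fit$history,
                 thresholds = thresholds, config = config,
                 teacher_fingerprint = model_fingerprint(teacher),
                 n_transfer = n_samples(sub), n_forget = if (has_forget) n_samples(fdata) else 0L,
                 teacher_test_accuracy = teacher_test_acc,
                 stop_reason = fit$stop_reason),
            class = "afs_kp")
}

#' @export
print.afs_kp <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat("<afs_kp> student:", x$student$spec$family,
      "(", format(count_parameters(x$student), big.mark = ","), "params )\n")
  cat("  transfer set:", x$n_transfer, "samples | forget set:", x$n_forget, "\n")
  cat("  epochs run:", nrow(x$trace),
      if (!is.na(x$stop_reason)) paste0("(", x$stop_reason, ")") else "", "\n")
  if (x$n_forget > 0) {
    cat("  final forget-set p:", format(last$p_forget, digits = 4), "\n")
  }
  if (!is.na(last$test_accuracy)) {
    cat("  final test accuracy:", sprintf("%.4f", last$test_accuracy),
        "(teacher:", sprintf("%.4f", x$teacher_test_accuracy), ")\n")
  }
  invisible(x)
}

#' Plot a knowledge-purification training trace
#'
#' Two stacked panels: the audit p-value of the forget set per epoch (log
#' scale, with the `target_p` line) and the loss components / beta schedule.
#'
#' @param x an `afs_kp`.
#' @param ... unused.
#' @export
plot.afs_kp <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  p <- pmax(tr$p_forget, 1e-300)
  graphics::plot(tr$epoch, log10(p), type = "b", pch = 16, cex = 0.6,
                 xlab = "epoch", ylab = "log10 p(forget)",
                 main = "audit of the forget set")
  graphics::abline(h = log10(x$config$target_p), lty = 2)
  graphics::matplot(tr$epoch, cbind(tr$hard, tr$kd, tr$forget), type = "l",
                    lty = 1, xlab = "epoch", ylab = "loss",
                    main = "loss components")
  graphics::legend("topright", c("hard", "kd", "forget"), lty = 1, col = 1:3,
                   bty = "n", cex = 0.8)
  invisible(x)
}
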