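# Reproducible end-to-end experiment protocol on the Gaussian-blob fixture.
# The protocol constants below define the study conditions every audit and
# forgetting experiment in the package runs under; tests and the acceptance
# script call these functions rather than re-assembling the pipeline.

#' Study conditions for the blob-fixture experiments
#'
#' The fixture is sized so that an over-parameterised MLP teacher memorises
#' its 1000-sample training split (train accuracy 1) while held-out accuracy
#' stays capped by class overlap -- the measurable overfitting gap the audit
#' exploits. A 2600-sample pool yields disjoint train (1000), test (500) and
#' calibration (500) splits plus a 600-sample held-out non-member pool.
#' Three classes with centres `2 * e_c` in 50 dimensions put the pairwise
#' Bayes error around 10-15 percent; the 47 noise dimensions make individual
#' training points easy to memorise. Training uses Adam for 50 epochs.
#'
#' @param ... named overrides of individual protocol constants.
#' @return a named list of protocol constants.
#' @export
blob_protocol <- function(...) {
  proto <- list(n_pool = 2600L, C = 3L, d = 50L, separation = 2,
                train_n = 1000L, test_n = 500L, cal_n = 500L,
                teacher_hidden = 256L, student_hidden = 64L,
                epochs = 50L, lr = 0.01, batch_size = 32L)
  over <- list(...)
  unknown <- setdiff(names(over), names(proto))
  if (length(unknown) > 0) stop("unknown protocol fields: ", paste(unknown, collapse = ", "))
  proto[names(over)] <- over
  proto
}

protocol_specs <- function(proto) {
  list(teacher = model_spec("mlp", proto$d, proto$C, hidden = proto$teacher_hidden),
       student = model_spec("mlp", proto$d, proto$C, hidden = proto$student_hidden))
}

#' Assemble the shared experimental context for one replicate
#'
#' Generates the pool, draws the splits, trains the teacher on the full
#' training split and calibrates audit thresholds with a shadow model of the
#' student architecture. Everything downstream (query audits, forgetting,
#' baselines) reuses this context.
#'
#' @param seed replicate seed.
#' @param proto a [blob_protocol()].
#' @return a list with `pool`, `splits`, `specs`, `teacher`, `thresholds`,
#'   and the teacher's train/test accuracy.
#' @export
audit_context <- function(seed, proto = blob_protocol()) {
  pool <- gen_gaussian_blobs(proto$n_pool, proto$C, proto$d,
                             separation = proto$separation, seed = seed)
  splits <- make_splits(pool, proto$train_n, proto$test_n, proto$cal_n, seed = seed)
  specs <- protocol_specs(proto)
  teacher <- train_independent(specs$teacher, splits$train, seed = seed,
                               epochs = proto$epochs, lr = proto$lr,
                               batch_size = proto$batch_size)
  thresholds <- calibrate(specs$student, splits$calibration,
                          epochs = proto$epochs, lr = proto$lr,
                          batch_size = proto$batch_size, seed = seed)
  list(pool = pool, splits = splits, specs = specs, teacher = teacher,
       thresholds = thresholds,
       teacher_train_accuracy = model_accuracy(teacher, splits$train),
       teacher_test_accuracy = model_accuracy(teacher, splits$test),
       seed = as.integer(seed), proto = proto)
}

#' Audit separation experiment (member vs non-member queries)
#'
#' Audits a QO query (drawn from the teacher's training split) and a QNO
#' query (drawn from the held-out pool) of the same size on the teacher.
#'
#' @param seed replicate seed.
#' @param size query size N.
#' @param proto a [blob_protocol()].
#' @param ctx optional precomputed [audit_context()].
#' @return a list with `p_member`, `p_nonmember` and the context.
#' @export
run_audit_experiment <- function(seed, size = 200L, proto = blob_protocol(),
                                 ctx = NULL) {
  if (is.null(ctx)) ctx <- audit_context(seed, proto)
  qo <- build_query(ctx$splits, "QO", size, seed = derive_seed(seed, 1L))
  qno <- build_query(ctx$splits, "QNO", size, seed = derive_seed(seed, 2L))
  a_o <- audit_dataset(ctx$teacher, qo, thresholds = ctx$thresholds, seed = seed)
  a_no <- audit_dataset(ctx$teacher, qno, thresholds = ctx$thresholds, seed = seed)
  list(p_member = a_o$p_value, p_nonmember = a_no$p_value,
       member_fraction_qo = a_o$member_fraction,
       member_fraction_qno = a_no$member_fraction, ctx = ctx)
}

#' Purity (QM) monotonicity experiment
#'
#' Audits QM queries of fixed size across a grid of member fractions k on
#' the teacher, with shared thresholds.
#'
#' @param seed replicate seed.
#' @param ks member-fraction grid.
#' @param size query size N.
#' @param proto a [blob_protocol()].
#' @param ctx optional precomputed [audit_context()].
#' @return named numeric vector of p-values, one per k.
#' @export
run_purity_experiment <- function(seed, ks = c(1, 0.75, 0.5, 0.25, 0),
                                  size = 200L, proto = blob_protocol(),
                                  ctx = NULL) {
  if (is.null(ctx)) ctx <- audit_context(seed, proto)
  p <- vapply(seq_along(ks), function(i) {
    qm <- build_query(ctx$splits, "QM", size, k = ks[i],
                      seed = derive_seed(seed, 10L + i))
    audit_dataset(ctx$teacher, qm, thresholds = ctx$thresholds, seed = seed)$p_value
  }, numeric(1))
  names(p) <- paste0("k=", ks)
  p
}

#' Forgetting experiment: knowledge purification vs its ablation
#'
#' Designates a QF forget set inside the training split, then compares
#' (i) the teacher (nothing forgotten), (ii) the audit-guided student
#' ([afs_train()]), (iii) the beta = 0 ablation (plain distillation on the
#' same retained fraction, no forget pressure), and (iv) an independent
#' student retrained from scratch on the same fraction with QF excluded.
#' All final audits of QF use the shared context thresholds.
#'
#' @param seed replicate seed.
#' @param qf_size forget-set size.
#' @param k retained fraction used for transfer / retraining.
#' @param proto a [blob_protocol()].
#' @param ctx optional precomputed [audit_context()].
#' @return a list of forget-set p-values and test accuracies per method.
#' @export
run_forget_experiment <- function(seed, qf_size = 100L, k = 0.5,
                                  proto = blob_protocol(), ctx = NULL) {
  if (is.null(ctx)) ctx <- audit_context(seed, proto)
  qf <- build_query(ctx$splits, "QF", qf_size, seed = derive_seed(seed, 3L))
  audit_qf <- function(model) {
    audit_dataset(model, qf, thresholds = ctx$thresholds, seed = seed)$p_value
  }
  cfg <- forget_config(k = k, seed = seed, epochs = ctx$proto$epochs,
                       lr = ctx$proto$lr, batch_size = ctx$proto$batch_size,
                       calibration_epochs = ctx$proto$epochs)
  kp <- afs_train(ctx$teacher, ctx$specs$student, ctx$splits$train, qf,
                  ctx$splits$calibration, config = cfg, test = ctx$splits$test)
  cfg_ab <- cfg; cfg_ab$beta_init <- 0
  ablation <- afs_train(ctx$teacher, ctx$specs$student, ctx$splits$train, qf,
                        ctx$splits$calibration, config = cfg_ab,
                        test = ctx$splits$test)
  indep <- train_independent(ctx$specs$student, ctx$splits$train, k = k,
                             exclude = qf, seed = seed,
                             epochs = ctx$proto$epochs, lr = ctx$proto$lr,
                             batch_size = ctx$proto$batch_size)
  list(p_teacher = audit_qf(ctx$teacher),
       p_afs = audit_qf(kp$student),
       p_ablation = audit_qf(ablation$student),
       p_independent = audit_qf(indep),
       acc_teacher = ctx$teacher_test_accuracy,
       acc_afs = model_accuracy(kp$student, ctx$splits$test),
       acc_ablation = model_accuracy(ablation$student, ctx$splits$test),
       acc_independent = model_accuracy(indep, ctx$splits$test),
       kp = kp, ctx = ctx)
}

#' Last-k-layer baseline experiment
#'
#' Compares CF-k fine-tuning of the teacher's output layer on the retain set
#' against full independent retraining with the forget set excluded, auditing
#' the forget set on both with shared thresholds.
#'
#' @param seed replicate seed.
#' @param qf_size forget-set size.
#' @param k_layers number of trailing layers CF-k fine-tunes.
#' @param proto a [blob_protocol()].
#' @param ctx optional precomputed [audit_context()].
#' @return a list with `p_cf`, `p_retrain` and the models.
#' @export
run_layer_baseline_experiment <- function(seed, qf_size = 100L, k_layers = 1L,
                                          proto = blob_protocol(), ctx = NULL) {
  if (is.null(ctx)) ctx <- audit_context(seed, proto)
  qf <- build_query(ctx$splits, "QF", qf_size, seed = derive_seed(seed, 3L))
  retain <- retain_set(ctx$splits$train, qf)
  cf <- cf_k(ctx$teacher, retain, k_layers, seed = seed,
             epochs = ctx$proto$epochs, lr = ctx$proto$lr,
             batch_size = ctx$proto$batch_size)
  retrain <- train_independent(ctx$specs$teacher, ctx$splits$train, k = 1,
                               exclude = qf, seed = seed,
                               epochs = ctx$proto$epochs, lr = ctx$proto$lr,
                               batch_size = ctx$proto$batch_size)
  audit_qf <- function(model) {
    audit_dataset(model, qf, thresholds = ctx$thresholds, seed = seed)$p_value
  }
  list(p_cf = audit_qf(cf), p_retrain = audit_qf(retrain),
       cf = cf, retrain = retrain, ctx = ctx)
}
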