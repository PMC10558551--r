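test_that("kd_loss matches hand-computed divergences", {
  # identical distributions
  p <- matrix(c(0.3, 0.7, 0.5, 0.5), 2, byrow = TRUE)
  expect_equal(kd_loss(p, p, temperature = 1), 0)
  # teacher one-hot, student uniform, T = 1, C = 2: KL = log 2
  expect_equal(kd_loss(matrix(c(0.5, 0.5), 1), matrix(c(1, 0), 1), 1), log(2))
  # direct KL oracle on random rows, including the T^2 scaling
  set.seed(5)
  s <- afs:::softmax(matrix(rnorm(12), 4))
  t_ <- afs:::softmax(matrix(rnorm(12), 4))
  want <- mean(vapply(1:4, function(i) sum(t_[i, ] * log(t_[i, ] / s[i, ])), numeric(1)))
  expect_equal(kd_loss(s, t_, 1), want, tolerance = 1e-12)
  expect_equal(kd_loss(s, t_, 2), 4 * want, tolerance = 1e-12)
  expect_true(kd_loss(s, t_, 2) >= 0)
  expect_error(kd_loss(s, t_[1:2, ]), "shapes")
})

test_that("forget_loss spans [0, log C] with the right extremes", {
  expect_equal(forget_loss(matrix(rep(0.25, 4), 1)), 0)
  expect_equal(forget_loss(matrix(c(1, 0, 0), 1)), log(3))
  # C = 2, rows (0.9, 0.1): log 2 - H(0.9) by direct entropy arithmetic
  h <- -(0.9 * log(0.9) + 0.1 * log(0.1))
  expect_equal(forget_loss(matrix(c(0.9, 0.1), 1)), log(2) - h, tolerance = 1e-12)
  expect_error(forget_loss(matrix(numeric(0), 0, 2)), "empty")
})

test_that("total_loss is the stated convex-plus-penalty combination", {
  expect_equal(total_loss(1, 2, 3, kd_weight = 0.5, beta = 0.1), 1.8)
  expect_equal(total_loss(1.7, 99, 99, kd_weight = 0, beta = 0), 1.7)
  expect_equal(total_loss(1, 2, 99, kd_weight = 0.3, beta = 0), 0.7 + 0.6)
})

test_that("forget_config validates its ranges", {
  expect_s3_class(forget_config(), "forget_config")
  expect_error(forget_config(kd_weight = 1.5), "kd_weight")
  expect_error(forget_config(temperature = 0), "temperature")
  expect_error(forget_config(epochs = 0), "epochs")
  expect_error(forget_config(k = 0), "k must")
})

test_that("with no forget set and beta 0, afs_train is exactly knowledge distillation", {
  proto <- small_proto()
  ctx <- audit_context(42, proto)
  cfg <- forget_config(k = 0.5, seed = 9, epochs = 6, lr = proto$lr,
                       batch_size = proto$batch_size, beta_init = 0)
  kp <- afs_train(ctx$teacher, ctx$specs$student, ctx$splits$train,
                  forget = NULL, calibration = ctx$splits$calibration,
                  config = cfg)
  # replicate the identical distillation run by hand with the shared primitives
  nr <- n_samples(ctx$splits$train)
  take <- as.integer(afs:::round_half_away(0.5 * nr))
  sub <- dataset_subset(ctx$splits$train,
                        afs:::with_seed(afs:::derive_seed(9, 999L),
                                        sample.int(nr, take)))
  manual <- afs:::train_core(build_model(ctx$specs$student, seed = 9), sub,
                             epochs = 6, lr = proto$lr,
                             batch_size = proto$batch_size, seed = 9,
                             teacher = ctx$teacher, kd_weight = cfg$kd_weight,
                             temperature = cfg$temperature)$model
  expect_identical(model_fingerprint(kp$student), model_fingerprint(manual))
  expect_equal(nrow(kp$trace), 6)
  expect_true(all(kp$trace$forget == 0))
})

test_that("afs_train bookkeeping: trace rows, determinism, smaller student", {
  proto <- small_proto()
  ctx <- audit_context(42, proto)
  qf <- build_query(ctx$splits, "QF", 20, seed = 5)
  cfg <- forget_config(k = 0.5, seed = 3, epochs = 5, lr = proto$lr,
                       batch_size = proto$batch_size,
                       calibration_epochs = proto$epochs)
  kp1 <- afs_train(ctx$teacher, ctx$specs$student, ctx$splits$train, qf,
                   ctx$splits$calibration, config = cfg, test = ctx$splits$test)
  kp2 <- afs_train(ctx$teacher, ctx$specs$student, ctx$splits$train, qf,
                   ctx$splits$calibration, config = cfg, test = ctx$splits$test)
  expect_identical(model_fingerprint(kp1$student), model_fingerprint(kp2$student))
  expect_lte(nrow(kp1$trace), 5)
  expect_true(all(kp1$trace$p_forget >= 0 & kp1$trace$p_forget <= 1))
  expect_true(all(diff(kp1$trace$epoch) == 1))
  if (nrow(kp1$trace) < 5) expect_identical(kp1$stop_reason, "forgotten_within_budget")
  expect_lt(count_parameters(kp1$student), count_parameters(ctx$teacher))
  # forget ids outside train are rejected
  bad <- dataset_subset(ctx$splits$test, 1:3)
  expect_error(afs_train(ctx$teacher, ctx$specs$student, ctx$splits$train, bad,
                         ctx$splits$calibration, config = cfg), "not present")
})

test_that("the beta feedback schedule rises while member-like and decays once forgotten", {
  proto <- small_proto()
  ctx <- audit_context(43, proto)
  qf <- build_query(ctx$splits, "QF", 20, seed = 6)
  cfg <- forget_config(k = 0.5, seed = 4, epochs = 12, lr = proto$lr,
                       batch_size = proto$batch_size,
                       calibration_epochs = proto$epochs,
                       beta_init = 0.5, beta_multiplier = 2, beta_cap = 8,
                       patience = 1000L)  # keep it running to observe the schedule
  kp <- afs_train(ctx$teacher, ctx$specs$student, ctx$splits$train, qf,
                  ctx$splits$calibration, config = cfg)
  tr <- kp$trace
  expect_true(all(tr$beta <= cfg$beta_cap & tr$beta >= cfg$beta_init))
  # feedback direction: beta recorded at epoch e+1 reflects the audit at e
  for (e in seq_len(nrow(tr) - 1)) {
    if (tr$p_forget[e] > cfg$target_p) {
      expect_equal(tr$beta[e + 1], min(tr$beta[e] * 2, cfg$beta_cap))
    } else {
      expect_equal(tr$beta[e + 1], max(tr$beta[e] / 2, cfg$beta_init))
    }
  }
})
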