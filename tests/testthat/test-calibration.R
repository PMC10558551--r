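test_that("balanced_accuracy counts TPR and TNR on the right sides", {
  expect_equal(balanced_accuracy(0.5, c(0.9, 0.8), c(0.1, 0.2), "ge"), 1)
  expect_equal(balanced_accuracy(0.45, c(0.9, 0.4), c(0.5, 0.1), "ge"), 0.5)
  # "le" member side (entropy direction)
  expect_equal(balanced_accuracy(0.3, c(0.1, 0.2), c(0.8, 0.9), "le"), 1)
  expect_error(balanced_accuracy(0.5, numeric(0), c(1), "ge"), "non-empty")
})

test_that("identical member and non-member distributions cap balanced accuracy at 0.5", {
  s <- c(0.2, 0.4, 0.6, 0.8)
  bt <- afs:::best_threshold(s, s, "ge")
  expect_equal(bt$balanced_accuracy, 0.5)
})

test_that("best_threshold matches the exhaustive grid-search oracle", {
  set.seed(202)
  for (rep in 1:200) {
    nm <- sample(1:50, 1); nn <- sample(1:50, 1)
    # mix of continuous and tied discrete scores
    member <- round(rnorm(nm, mean = runif(1, 0, 1)), sample(1:3, 1))
    nonmember <- round(rnorm(nn, mean = runif(1, 0, 1)), sample(1:3, 1))
    dir <- sample(c("ge", "le"), 1)
    got <- afs:::best_threshold(member, nonmember, dir)
    want <- oracle_best_threshold(member, nonmember, dir)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$balanced_accuracy, want$balanced_accuracy)
    # optimality: no other candidate beats the returned threshold
    expect_true(all(vapply(afs:::threshold_candidates(c(member, nonmember)),
                           balanced_accuracy, numeric(1),
                           member_scores = member, nonmember_scores = nonmember,
                           direction = dir) <= got$balanced_accuracy))
  }
})

test_that("the optimal balanced accuracy is invariant to monotone rescaling", {
  set.seed(9)
  member <- runif(30); nonmember <- runif(25)
  base <- afs:::best_threshold(member, nonmember, "ge")$balanced_accuracy
  resc <- afs:::best_threshold(exp(3 * member), exp(3 * nonmember), "ge")$balanced_accuracy
  expect_equal(resc, base)
})

test_that("infer_thresholds separates separable scores and covers all classes", {
  set.seed(4)
  n <- 60
  mk <- function(conf, ent, labels) {
    df <- data.frame(id = sprintf("x%03d", seq_along(labels)), label = labels,
                     correctness = 1L, confidence = conf, entropy = ent)
    attr(df, "num_classes") <- 3L
    class(df) <- c("metric_matrix", class(df))
    df
  }
  labels <- rep(0:2, each = n / 3)
  member <- mk(runif(n, 0.8, 1.0), runif(n, 0, 0.2), labels)
  nonmember <- mk(runif(n, 0.0, 0.5), runif(n, 0.5, 1.0), labels)
  ts <- infer_thresholds(member, nonmember)
  expect_s3_class(ts, "threshold_set")
  for (cl in 0:2) {
    tc <- resolve_threshold(ts, "confidence", cl)
    te <- resolve_threshold(ts, "entropy", cl)
    expect_true(tc > 0.5 && tc < 0.8)
    expect_true(te > 0.2 && te < 0.5)
  }
  # perfectly separated => balanced accuracy 1 at the chosen thresholds
  expect_equal(ts$metrics$confidence$fallback_balanced_accuracy, 1)
  expect_equal(ts$metrics$entropy$fallback_balanced_accuracy, 1)
})

test_that("classes with thin calibration support fall back to the pooled threshold", {
  mk <- function(conf, labels) {
    df <- data.frame(id = sprintf("y%03d", seq_along(labels)), label = labels,
                     correctness = 1L, confidence = conf,
                     entropy = 1 - conf)
    attr(df, "num_classes") <- 3L
    class(df) <- c("metric_matrix", class(df))
    df
  }
  # class 2 present only on the member side (and thinly)
  member <- mk(c(runif(20, 0.8, 1), 0.95, 0.9), c(rep(0:1, 10), 2L, 2L))
  nonmember <- mk(runif(20, 0, 0.4), rep(0:1, 10))
  ts <- infer_thresholds(member, nonmember, min_per_side = 5)
  expect_true(is.na(ts$metrics$confidence$per_class[3]))
  expect_equal(resolve_threshold(ts, "confidence", 2),
               ts$metrics$confidence$fallback)
  # classes with support resolve to their own thresholds
  expect_false(is.na(ts$metrics$confidence$per_class[1]))
  expect_error(infer_thresholds(member[0, ], nonmember), "non-empty")
})

test_that("train_calibration_model is seeded, supports epochs = 0, and learns", {
  cal <- gen_gaussian_blobs(120, C = 3, d = 6, separation = 5, seed = 21)
  spec <- model_spec("mlp", 6, 3, hidden = 16)
  a <- train_calibration_model(spec, cal, epochs = 10, seed = 5)
  b <- train_calibration_model(spec, cal, epochs = 10, seed = 5)
  expect_identical(model_fingerprint(a), model_fingerprint(b))
  # epochs = 0 returns the untouched initialised model
  m0 <- train_calibration_model(spec, cal, epochs = 0, seed = 5)
  expect_identical(model_fingerprint(m0),
                   model_fingerprint(build_model(spec, seed = 5)))
  # well-separated blobs are learnable
  expect_gte(afs:::model_accuracy(a, cal), 0.9)
  expect_error(train_calibration_model(spec, dataset_subset(cal, integer(0))),
               "non-empty")
})

test_that("calibrate splits 50/50, is deterministic, and overfits give high confidence thresholds", {
  cal <- gen_gaussian_blobs(200, C = 3, d = 20, separation = 2, seed = 31)
  spec <- model_spec("mlp", 20, 3, hidden = 64)
  ts <- calibrate(spec, cal, epochs = 30, seed = 2)
  expect_equal(ts$provenance$n_member, 100)
  expect_equal(ts$provenance$n_nonmember, 100)
  ts2 <- calibrate(spec, cal, epochs = 30, seed = 2)
  expect_equal(ts$metrics$confidence$per_class, ts2$metrics$confidence$per_class)
  expect_identical(ts$provenance$shadow_fingerprint, ts2$provenance$shadow_fingerprint)
  # the shadow model memorises its half: member confidence thresholds sit
  # well above the uniform level 1/C for every populated class
  for (cl in 0:2) {
    expect_gt(resolve_threshold(ts, "confidence", cl), 1 / 3)
  }
  expect_error(calibrate(spec, dataset_subset(cal, 1)), "at least 2")
})

test_that("threshold sets survive a JSON round trip", {
  cal <- gen_gaussian_blobs(80, C = 2, d = 4, separation = 3, seed = 8)
  spec <- model_spec("mlp", 4, 2, hidden = 8)
  ts <- calibrate(spec, cal, epochs = 5, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_thresholds_json(ts, path)
  back <- read_thresholds_json(path)
  for (m in c("confidence", "entropy")) {
    expect_equal(back$metrics[[m]]$per_class, ts$metrics[[m]]$per_class)
    expect_equal(back$metrics[[m]]$fallback, ts$metrics[[m]]$fallback)
    expect_equal(back$metrics[[m]]$direction, ts$metrics[[m]]$direction)
  }
  expect_equal(back$correctness$threshold, 0.5)
  expect_equal(resolve_threshold(back, "entropy", 1),
               resolve_threshold(ts, "entropy", 1))
})
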