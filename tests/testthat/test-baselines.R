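test_that("train_independent subsampling arithmetic and determinism", {
  proto <- small_proto()
  data <- gen_gaussian_blobs(200, C = 3, d = 6, separation = 3, seed = 2)
  spec <- model_spec("mlp", 6, 3, hidden = 8)
  a <- train_independent(spec, data, k = 1, seed = 1, epochs = 4)
  b <- train_independent(spec, data, k = 1, seed = 1, epochs = 4)
  expect_identical(model_fingerprint(a), model_fingerprint(b))
  expect_error(train_independent(spec, data, k = 1e-9, seed = 1), "empty")
})

test_that("SISA shards partition the training ids", {
  data <- gen_gaussian_blobs(150, C = 3, d = 6, separation = 3, seed = 3)
  spec <- model_spec("mlp", 6, 3, hidden = 8)
  sm <- sisa_train(spec, data, shards = 5, seed = 1, epochs = 2)
  expect_setequal(names(sm$shard_of), data$ids)
  expect_true(all(sm$shard_of %in% 0:4))
  # disjoint and covering by construction of a single assignment vector
  expect_equal(length(sm$shard_of), n_samples(data))
})

test_that("SISA unlearning retrains only affected shards and is idempotent", {
  data <- gen_gaussian_blobs(150, C = 3, d = 6, separation = 3, seed = 4)
  spec <- model_spec("mlp", 6, 3, hidden = 8)
  sm <- sisa_train(spec, data, shards = 5, seed = 2, epochs = 2)
  before <- vapply(sm$models, model_fingerprint, character(1))
  # forget ids confined to known shards
  ids_shard0 <- names(sm$shard_of)[sm$shard_of == 0][1:3]
  forget1 <- dataset_subset(data, ids_shard0)
  un1 <- sisa_unlearn(sm, forget1)
  after1 <- vapply(un1$models, model_fingerprint, character(1))
  expect_false(identical(after1[1], before[1]))
  expect_identical(after1[2:5], before[2:5])  # untouched shards bitwise equal
  expect_false(any(ids_shard0 %in% names(un1$shard_of)))
  # spread over three shards: exactly those three retrained
  pick <- c(names(sm$shard_of)[sm$shard_of == 1][1],
            names(sm$shard_of)[sm$shard_of == 2][1],
            names(sm$shard_of)[sm$shard_of == 3][1])
  un3 <- sisa_unlearn(sm, dataset_subset(data, pick))
  after3 <- vapply(un3$models, model_fingerprint, character(1))
  expect_identical(after3[c(1, 5)], before[c(1, 5)])
  expect_false(any(after3[2:4] == before[2:4]))
  # idempotence: unlearning the same set from the shards again is a no-op
  un1b <- sisa_unlearn(sisa_train(spec, data, shards = 5, seed = 2, epochs = 2),
                       forget1)
  expect_identical(vapply(un1b$models, model_fingerprint, character(1)), after1)
  expect_error(sisa_unlearn(sm, labeled_dataset(matrix(0, 1, 6), 0, 3,
                                                ids = "nope")), "not mapped")
})

test_that("SISA aggregation equals the brute-force vote rule", {
  data <- gen_gaussian_blobs(120, C = 3, d = 6, separation = 3, seed = 5)
  spec <- model_spec("mlp", 6, 3, hidden = 8)
  sm <- sisa_train(spec, data, shards = 4, seed = 3, epochs = 2)
  batch <- data$features[1:15, ]
  got <- sisa_predict(sm, batch)
  # loop oracle: count arg-max votes of every shard model
  counts <- matrix(0, 15, 3)
  for (m in sm$models) {
    cls <- predict(m, batch, type = "class")
    for (i in 1:15) counts[i, cls[i] + 1] <- counts[i, cls[i] + 1] + 1
  }
  expect_equal(got, counts / length(sm$models))
  expect_equal(rowSums(got), rep(1, 15))
  # classifier wrapper exposes the standard contract
  clf <- as_classifier(sm)
  expect_equal(predict(clf, batch, type = "prob"), got)
  mm <- metric_matrix(clf, dataset_subset(data, 1:15))
  expect_equal(nrow(mm), 15)
})

test_that("CF-k freezes everything outside the last k layers", {
  data <- gen_gaussian_blobs(150, C = 3, d = 6, separation = 3, seed = 6)
  spec <- model_spec("mlp", 6, 3, hidden = c(16, 8))
  m <- train_independent(spec, data, seed = 1, epochs = 3)
  before <- afs:::layer_fingerprints(m)
  ft <- cf_k(m, data, k_layers = 1, seed = 2, epochs = 3)
  after <- afs:::layer_fingerprints(ft)
  expect_identical(after[1:2], before[1:2])   # frozen groups bitwise equal
  expect_false(identical(after[3], before[3]))  # only the output layer moved
  # boundary: k = depth is a full fine-tune (every group moves)
  full <- cf_k(m, data, k_layers = 3, seed = 2, epochs = 3)
  expect_true(all(afs:::layer_fingerprints(full) != before))
  expect_error(cf_k(m, data, k_layers = 4), "k_layers")
  expect_error(cf_k(m, data, k_layers = 0), "k_layers")
})

test_that("EU-k re-initialises before retraining and reduces to full retraining at depth", {
  data <- gen_gaussian_blobs(150, C = 3, d = 6, separation = 3, seed = 7)
  spec <- model_spec("mlp", 6, 3, hidden = 16)
  m <- train_independent(spec, data, seed = 1, epochs = 3)
  before <- afs:::layer_fingerprints(m)
  # frozen layers unchanged; the re-initialised head differs from the
  # original even before training (fresh seeded draws)
  eu <- eu_k(m, data, k_layers = 1, seed = 9, epochs = 3)
  after <- afs:::layer_fingerprints(eu)
  expect_identical(after[1], before[1])
  expect_false(identical(after[2], before[2]))
  fresh <- build_model(spec, seed = 9)
  expect_false(identical(afs:::layer_fingerprints(fresh)[2], before[2]))
  # k = depth: identical to independent training from scratch, same seed
  eu_full <- eu_k(m, data, k_layers = 2, seed = 4, epochs = 3)
  indep <- train_independent(spec, data, k = 1, seed = 4, epochs = 3)
  expect_identical(model_fingerprint(eu_full), model_fingerprint(indep))
})
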