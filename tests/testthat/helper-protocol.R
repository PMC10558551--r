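# Shared experiment contexts, built lazily and memoised so the audit and
# acceptance tests reuse one teacher/threshold set per replicate seed.

.ctx_cache <- new.env(parent = emptyenv())

get_ctx <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(.ctx_cache[[key]])) .ctx_cache[[key]] <- audit_context(seed)
  .ctx_cache[[key]]
}

# A scaled-down protocol for fast unit-level end-to-end checks.
small_proto <- function() {
  blob_protocol(n_pool = 420L, train_n = 150L, test_n = 80L, cal_n = 100L,
                teacher_hidden = 64L, student_hidden = 32L, epochs = 15L)
}

# Tiny deterministic "model" wrapper: an mlp trained a little on blobs,
# for tests that just need a conforming probabilistic classifier.
tiny_model_and_data <- function(seed = 1, n = 60, C = 3, d = 6) {
  data <- gen_gaussian_blobs(n, C = C, d = d, separation = 3, seed = seed)
  spec <- model_spec("mlp", d, C, hidden = 8)
  model <- afs:::fit_classifier(spec, data, epochs = 5, lr = 0.01, seed = seed)
  list(model = model, data = data, spec = spec)
}
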