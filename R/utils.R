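# Internal helpers shared across the package.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic entry points route their randomness through this.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from (seed, stream index); kept well below 2^31.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483587)
}

# Numerically stable row-wise softmax of a logit matrix.
softmax <- function(z) {
  z <- as.matrix(z)
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Shannon entropy (nats) of each row of a probability matrix; 0*log(0) := 0.
row_entropy <- function(p) {
  p <- as.matrix(p)
  lp <- ifelse(p > 0, log(p), 0)
  -rowSums(p * lp)
}

# Row-wise arg-max with lowest-index tie-break, 0-based classes.
row_argmax <- function(p) {
  max.col(as.matrix(p), ties.method = "first") - 1L
}

# Stable content hash of an R object (used for model fingerprints).
content_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
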