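test_that("audit_pvalue matches the pooled-t oracle for every one-count at N = 100", {
  N <- 100
  for (ones in 0:N) {
    votes <- rep(c(1, 0), c(ones, N - ones))
    got <- audit_pvalue(votes)
    if (ones == N) {
      expect_equal(got, 1)
    } else if (ones == 0) {
      expect_equal(got, 0)
    } else {
      expect_equal(got, oracle_pooled_t_p(votes), tolerance = 1e-12)
      # independent statistics oracle
      ref <- t.test(votes, rep(1, N), var.equal = TRUE)$p.value
      expect_equal(got, ref, tolerance = 1e-9)
    }
  }
})

test_that("audit_pvalue is monotone in the number of member votes", {
  N <- 100
  p <- vapply(0:N, function(ones) audit_pvalue(rep(c(1, 0), c(ones, N - ones))),
              numeric(1))
  expect_true(all(diff(p) >= 0))  # more ones => larger (more member-like) p
})

test_that("audit_pvalue handles degenerate inputs", {
  expect_equal(audit_pvalue(rep(1, 7)), 1)
  expect_equal(audit_pvalue(rep(0, 7)), 0)
  expect_equal(audit_pvalue(1), 1)
  expect_equal(audit_pvalue(0), 0)
  expect_error(audit_pvalue(numeric(0)), "empty")
  # spec'd worked value: 80 ones, 20 zeros at N = 100
  expect_equal(audit_pvalue(rep(c(1, 0), c(80, 20))), 1.4e-6,
               tolerance = 0.05)
})

test_that("the OR rule matches enumeration of all 8 indicator patterns", {
  # thresholds chosen so each metric's vote can be forced either way
  mk_ts <- function() {
    structure(list(
      metrics = list(
        confidence = list(direction = "ge", per_class = c(0.7, 0.7),
                          fallback = 0.7),
        entropy = list(direction = "le", per_class = c(0.3, 0.3),
                       fallback = 0.3)),
      correctness = list(threshold = 0.5, direction = "ge"),
      num_classes = 2L, min_per_side = 5L, provenance = list()),
      class = "threshold_set")
  }
  ts <- mk_ts()
  for (corr in 0:1) for (conf_hi in 0:1) for (ent_lo in 0:1) {
    conf <- if (conf_hi) 0.9 else 0.1
    ent <- if (ent_lo) 0.1 else 0.9
    got <- sample_membership(corr, conf, ent, y = 1, thresholds = ts)
    expect_identical(got, as.integer(corr == 1 || conf_hi == 1 || ent_lo == 1))
    # vectorised path agrees
    mm <- data.frame(id = "a", label = 1L, correctness = corr,
                     confidence = conf, entropy = ent)
    attr(mm, "num_classes") <- 2L
    v <- membership_votes(mm, ts)
    expect_identical(v$vote, got)
    expect_identical(v$vote_correctness, as.integer(corr == 1))
    expect_identical(v$vote_confidence, as.integer(conf_hi == 1))
    expect_identical(v$vote_entropy, as.integer(ent_lo == 1))
  }
})

test_that("audit_dataset wires the pipeline and flags low power", {
  proto <- small_proto()
  ctx <- audit_context(101, proto)
  qo <- build_query(ctx$splits, "QO", 50, seed = 1)
  a <- audit_dataset(ctx$teacher, qo, thresholds = ctx$thresholds)
  expect_s3_class(a, "afs_audit")
  expect_true(a$p_value >= 0 && a$p_value <= 1)
  expect_false(a$low_power)
  expect_equal(a$n_query, 50)
  expect_identical(a$verdict,
                   if (a$p_value >= a$alpha) "member-like" else "non-member-like")
  expect_equal(a$member_fraction, mean(a$votes$vote))
  # single-sample query carries the low-power flag
  q1 <- build_query(ctx$splits, "QO", 1, seed = 2)
  a1 <- audit_dataset(ctx$teacher, q1, thresholds = ctx$thresholds)
  expect_true(a1$low_power)
  # errors
  expect_error(audit_dataset(ctx$teacher, dataset_subset(ctx$pool, integer(0)),
                             thresholds = ctx$thresholds), "empty")
  wrongC <- gen_gaussian_blobs(30, C = 4, d = proto$d, separation = 2, seed = 1)
  expect_error(audit_dataset(ctx$teacher, wrongC, thresholds = ctx$thresholds),
               "class count")
  expect_error(audit_dataset(ctx$teacher, qo), "calibration")
})

test_that("audit_dataset is deterministic under fixed seeds", {
  proto <- small_proto()
  ctx <- audit_context(77, proto)
  q <- build_query(ctx$splits, "QM", 40, k = 0.5, seed = 5)
  a <- audit_dataset(ctx$teacher, q, calibration = ctx$splits$calibration,
                     arch = ctx$specs$student, epochs = proto$epochs, seed = 3)
  b <- audit_dataset(ctx$teacher, q, calibration = ctx$splits$calibration,
                     arch = ctx$specs$student, epochs = proto$epochs, seed = 3)
  expect_equal(a$p_value, b$p_value)
  expect_identical(a$votes$vote, b$votes$vote)
})

test_that("query size amplifies the separation between member and non-member audits", {
  # the p-value gap between a member query and a non-member query widens
  # with query size (mean over the five replicate seeds)
  gaps <- vapply(0:4, function(seed) {
    ctx <- get_ctx(seed)
    g <- function(size) {
      r <- run_audit_experiment(seed, size = size, ctx = ctx)
      r$p_member - r$p_nonmember
    }
    c(small = g(10L), large = g(500L))
  }, numeric(2))
  expect_gte(mean(gaps["large", ]), mean(gaps["small", ]))
})

test_that("audit reports serialize to JSON", {
  proto <- small_proto()
  ctx <- audit_context(55, proto)
  q <- build_query(ctx$splits, "QNO", 30, seed = 1)
  a <- audit_dataset(ctx$teacher, q, thresholds = ctx$thresholds)
  path <- withr::local_tempfile(fileext = ".json")
  write_audit_json(a, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$p_value, a$p_value)
  expect_equal(back$n_query, 30)
  expect_identical(back$verdict, a$verdict)
})
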