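# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / closed form, never by calling the code paths
# they check.

# Closed-form pooled two-sample t-test of a 0/1 vector against an all-one
# vector of equal length (df = 2N - 2).
oracle_pooled_t_p <- function(votes) {
  n <- length(votes)
  m <- sum(votes) / n
  ss <- sum((votes - m)^2)
  sp2 <- ss / (2 * n - 2)
  if (sp2 == 0) return(if (m == 1) 1 else 0)
  tstat <- (m - 1) / sqrt(sp2 * (1 / n + 1 / n))
  2 * pt(-abs(tstat), df = 2 * n - 2)
}

# Exhaustive grid search for the balanced-accuracy-optimal threshold:
# candidates are midpoints of consecutive sorted unique pooled scores plus
# sentinels, TPR/TNR counted explicitly, smallest maximiser returned.
oracle_best_threshold <- function(member, nonmember, direction) {
  s <- sort(unique(c(member, nonmember)))
  cand <- if (length(s) == 1L) c(s - 1, s + 1) else
    c(s[1] - 1, (s[-length(s)] + s[-1]) / 2, s[length(s)] + 1)
  best_t <- NA_real_; best_b <- -Inf
  for (t in cand) {
    if (direction == "ge") {
      tpr <- sum(member >= t) / length(member)
      tnr <- sum(nonmember < t) / length(nonmember)
    } else {
      tpr <- sum(member <= t) / length(member)
      tnr <- sum(nonmember > t) / length(nonmember)
    }
    b <- (tpr + tnr) / 2
    if (b > best_b) { best_b <- b; best_t <- t }
  }
  list(threshold = best_t, balanced_accuracy = best_b)
}

# Per-sample metric recomputation with plain loops.
oracle_metric_rows <- function(probs, labels) {
  n <- nrow(probs)
  corr <- integer(n); conf <- numeric(n); ent <- numeric(n)
  for (i in seq_len(n)) {
    p <- probs[i, ]
    corr[i] <- as.integer((which.max(p) - 1L) == labels[i])
    conf[i] <- p[labels[i] + 1L]
    ent[i] <- -sum(ifelse(p > 0, p * log(p), 0))
  }
  list(correctness = corr, confidence = conf, entropy = ent)
}

# Macro F1 by explicit per-class loops over a confusion table.
oracle_macro_f1 <- function(cm) {
  C <- nrow(cm)
  vals <- numeric(C)
  for (cl in seq_len(C)) {
    tp <- cm[cl, cl]; fp <- sum(cm[, cl]) - tp; fn <- sum(cm[cl, ]) - tp
    den <- 2 * tp + fp + fn
    vals[cl] <- if (den == 0) 0 else 2 * tp / den
  }
  mean(vals)
}
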