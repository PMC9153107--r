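# Independent oracles, deliberately naive: each re-derives a quantity by
# enumeration or first principles, sharing no code with the implementation.

# Per-column percentile by explicit sort-then-assign with manual tie
# averaging (no rank()).
oracle_rank_percentile <- function(mat) {
  G <- nrow(mat)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    ranks <- numeric(G)
    for (i in seq_len(G)) {
      below <- sum(col < col[i])
      tied <- sum(col == col[i])
      # average of competition ranks (below+1) ... (below+tied)
      ranks[i] <- below + (tied + 1) / 2
    }
    out[, j] <- 100 * (ranks - 1) / (G - 1)
  }
  out
}

# Weighted Gini of a candidate split: y 0/1, go_high logical.
oracle_split_gini <- function(y, go_high) {
  n <- length(y)
  gini <- function(part) {
    if (!length(part)) return(0)
    p <- mean(part)
    2 * p * (1 - p)
  }
  (sum(!go_high) * gini(y[!go_high]) + sum(go_high) * gini(y[go_high])) / n
}

# Exhaustive search over every (feature, midpoint-between-distinct-values)
# pair honoring a min_leaf constraint. X: samples x features; returns the
# minimal weighted Gini or NA if no admissible split exists.
oracle_best_gini <- function(X, y, min_leaf = 1L) {
  best <- NA_real_
  for (j in seq_len(ncol(X))) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2L) next
    for (i in seq_len(length(v) - 1L)) {
      thr <- (v[i] + v[i + 1L]) / 2
      hi <- X[, j] >= thr
      if (sum(hi) < min_leaf || sum(!hi) < min_leaf) next
      g <- oracle_split_gini(y, hi)
      if (is.na(best) || g < best) best <- g
    }
  }
  best
}

# Mann-Whitney AUC by explicit pair counting, ties worth 1/2.
oracle_auc <- function(y, scores) {
  pos <- scores[y == 1L]
  neg <- scores[y == 0L]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# F1 from first principles.
oracle_f1 <- function(y, pred) {
  tp <- sum(y == 1 & pred == 1)
  fp <- sum(y == 0 & pred == 1)
  fn <- sum(y == 1 & pred == 0)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}
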