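# Independent oracles and tiny fixture builders used across the suite.

# Exact two-sided rank-sum p-value by full enumeration of group splits.
enum_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  splits <- utils::combn(n, length(x))
  w_obs <- sum(r[seq_along(x)])
  w_all <- apply(splits, 2, function(idx) sum(r[idx]))
  mu <- length(x) * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Benjamini-Hochberg step-up from the definition.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  ranked <- p[o] * m / seq_len(m)
  # step-up: running minimum from the largest rank down
  adj[o] <- rev(cummin(rev(ranked)))
  pmin(adj, 1)
}

# CH index from the pairwise-distance identity:
# SS_W = sum over clusters of (sum_{i<j in C} d_ij^2) / |C|, SS_T likewise
# over all points, SS_B = SS_T - SS_W.
ch_from_distances <- function(d2, assignment) {
  n <- nrow(d2)
  k <- length(unique(assignment))
  ss_t <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (cl in unique(assignment)) {
    idx <- which(assignment == cl)
    sub <- d2[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ((ss_t - ss_w) / (k - 1)) / (ss_w / (n - k))
}

# Exhaustive k-medoid optimum for tiny instances.
brute_pam_cost <- function(dist, k) {
  n <- nrow(dist)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(dist[, med, drop = FALSE], 1, min))
    best <- min(best, cost)
  }
  best
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# small counts table fixture
tiny_table <- function(values, kind = "counts", taxonomy = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("F%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  abundance_table(values, kind = kind, taxonomy = taxonomy)
}
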