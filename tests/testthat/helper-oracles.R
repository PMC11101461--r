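# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: subset enumeration for cliques, the textbook
# risk-table formula for the log-rank statistic, and direct U-statistic /
# closed-form computations elsewhere.

# All maximal cliques (size >= 2) of an undirected adjacency matrix by
# exhaustive subset search over vertex bitmasks; feasible for n <= 15.
bf_maximal_cliques <- function(adj) {
  n <- nrow(adj)
  stopifnot(n <= 15)
  bit <- 2^(seq_len(n) - 1)
  nbr <- vapply(seq_len(n), function(v) sum(bit[adj[v, ] == 1]), numeric(1))
  out <- list()
  for (code in seq_len(2^n - 1)) {
    members <- which(bitwAnd(code, bit) > 0)
    if (length(members) < 2) next
    # clique: every member is adjacent to all the others
    ok <- all(vapply(members, function(v) {
      rest <- code - bit[v]
      bitwAnd(rest, nbr[v]) == rest
    }, logical(1)))
    if (!ok) next
    outside <- setdiff(seq_len(n), members)
    extendable <- any(vapply(outside, function(v) {
      bitwAnd(code, nbr[v]) == code
    }, logical(1)))
    if (!extendable) out[[length(out) + 1]] <- members
  }
  out
}

# MCC by brute force: sum of (|C| - 1)! over maximal cliques through each node.
bf_mcc <- function(adj) {
  n <- nrow(adj)
  score <- numeric(n)
  for (cl in bf_maximal_cliques(adj)) {
    score[cl] <- score[cl] + factorial(length(cl) - 1)
  }
  names(score) <- rownames(adj)
  score
}

# Two-group log-rank chi-square from the risk-set table (hypergeometric
# variance, ties grouped by event time).
logrank_oracle <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  stopifnot(nlevels(group) == 2)
  g1 <- group == levels(group)[1]
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & g1)
    d_j <- sum(time == t & event == 1)
    d1_j <- sum(time == t & event == 1 & g1)
    o_minus_e <- o_minus_e + d1_j - d_j * n1_j / n_j
    if (n_j > 1) {
      v <- v + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    }
  }
  o_minus_e^2 / v
}

# A tiny two-view toy: each view carries one of two orthogonal 2-block splits
# over 4 latent groups of `per` patients each.
orthogonal_views <- function(per = 8, hi = 0.9, lo = 0.1) {
  n <- 4 * per
  g <- rep(1:4, each = per)
  ids <- sprintf("P%02d", seq_len(n))
  block_w <- function(split) {
    w <- matrix(lo, n, n, dimnames = list(ids, ids))
    same <- outer(split, split, "==")
    w[same] <- hi
    diag(w) <- 1
    w
  }
  list(
    views = list(block_w(g %in% c(1, 2)), block_w(g %in% c(1, 3))),
    groups = g
  )
}

# Small planted cohort spec used by several tests.
small_spec <- function(seed = 11, ...) {
  cohort_spec(
    n_patients = 80,
    n_features = c(methylation = 600, mrna = 600, mirna = 150),
    seed = seed,
    ...
  )
}
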