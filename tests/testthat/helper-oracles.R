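# Independent oracles, deliberately written along different routes than
# the package implementation.

# PERMANOVA via the centered Gower matrix: SS_T = tr(G),
# SS_B = sum_g 1_g' G 1_g / n_g (G doubly centered). The package instead
# sums squared pairwise distances within groups.
oracle_permanova_stats <- function(d, labels) {
  m <- as.matrix(d)
  n <- nrow(m)
  a <- length(unique(labels))
  g <- -0.5 * m^2
  g <- sweep(g, 1, rowMeans(g))
  g <- sweep(g, 2, colMeans(g))
  ss_t <- sum(diag(g))
  ss_b <- 0
  for (lv in unique(labels)) {
    idx <- labels == lv
    ss_b <- ss_b + sum(g[idx, idx]) / sum(idx)
  }
  f <- (ss_b / (a - 1)) / ((ss_t - ss_b) / (n - a))
  list(F = f, R2 = ss_b / ss_t)
}

# exhaustive permutation p over all n! index permutations
oracle_permanova_exhaustive_p <- function(d, labels) {
  m <- as.matrix(d)
  n <- nrow(m)
  perms <- all_permutations(n)
  obs <- oracle_permanova_stats(m, labels)$F
  fs <- vapply(perms, function(ix) {
    oracle_permanova_stats(m, labels[ix])$F
  }, numeric(1))
  mean(fs >= obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- vector("list", n * length(sub))
  k <- 1
  for (i in seq_len(n)) {
    for (s in sub) {
      rest <- seq_len(n)[-i]
      out[[k]] <- c(i, rest[s])
      k <- k + 1
    }
  }
  out
}

# upper-tail hypergeometric by direct combinatorial sum
oracle_hyper_upper <- function(k, K, N, n) {
  js <- k:min(n, K)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# adjusted Rand index from the contingency table
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Newman modularity of a partition of an undirected simple graph
oracle_modularity <- function(edges_mat, membership) {
  m <- nrow(edges_mat)
  deg <- table(factor(c(edges_mat[, 1], edges_mat[, 2]),
                      levels = names(membership)))
  q <- 0
  for (cl in unique(membership)) {
    nodes <- names(membership)[membership == cl]
    within <- sum(edges_mat[, 1] %in% nodes & edges_mat[, 2] %in% nodes)
    dc <- sum(deg[nodes])
    q <- q + within / m - (dc / (2 * m))^2
  }
  q
}

# best 2-partition of a small graph by exhaustive modularity enumeration
oracle_best_bipartition <- function(edges_mat, nodes) {
  n <- length(nodes)
  best_q <- -Inf
  best <- NULL
  for (code in 0:(2^(n - 1) - 1)) {
    side <- c(0L, as.integer(intToBits(code))[seq_len(n - 1)])
    memb <- stats::setNames(side, nodes)
    q <- oracle_modularity(edges_mat, memb)
    if (q > best_q) {
      best_q <- q
      best <- memb
    }
  }
  list(membership = best, modularity = best_q)
}
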