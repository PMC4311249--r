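# Independent oracles used across the test files. These deliberately use
# different algorithms from the package implementation (brute-force
# enumeration, direct pair counting, stock R routines) so that agreement is
# meaningful.

# All labelled trees on n nodes via Prufer sequences; returns the minimum
# spanning-tree weight of the complete graph weighted by `w` by exhaustive
# enumeration. Feasible for n <= 6 (n^(n-2) trees).
oracle_mst_weight <- function(w) {
  n <- nrow(w)
  if (n == 2) return(w[1, 2])
  prufer_decode <- function(seq_, n) {
    degree <- rep(1L, n)
    for (s in seq_) degree[s] <- degree[s] + 1L
    edges <- matrix(0L, n - 1, 2)
    ptr <- 0
    for (k in seq_along(seq_)) {
      leaf <- min(which(degree == 1L))
      edges[k, ] <- c(leaf, seq_[k])
      degree[leaf] <- 0L
      degree[seq_[k]] <- degree[seq_[k]] - 1L
    }
    edges[n - 1, ] <- which(degree == 1L)
    edges
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    ed <- prufer_decode(grid[r, ], n)
    tw <- sum(w[ed])
    if (tw < best) best <- tw
  }
  best
}

# Four-point condition: of the three pairings of a quartet, the two largest
# sums must be equal (within tolerance).
four_point_ok <- function(K, i, j, k, l, tol = 1e-9) {
  s <- sort(c(K[i, j] + K[k, l], K[i, k] + K[j, l], K[i, l] + K[j, k]))
  abs(s[3] - s[2]) < tol
}

# Exact two-sided rank-sum p-value by direct pair counting over all
# assignments (independent of the implementation's rank-sum statistic).
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_stat <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  mu <- na * length(b) / 2
  obs <- abs(u_stat(a, b) - mu)
  sets <- utils::combn(length(pooled), na)
  stats <- apply(sets, 2, function(ix) {
    abs(u_stat(pooled[ix], pooled[-ix]) - mu)
  })
  mean(stats >= obs - 1e-12)
}

# Exhaustive C-score: direct delta-counting over all cross pairs.
oracle_cscore <- function(projection, labels) {
  labs <- unique(as.character(labels))
  prs <- utils::combn(labs, 2, simplify = FALSE)
  mean(vapply(prs, function(pr) {
    a <- projection[labels == pr[1]]
    b <- projection[labels == pr[2]]
    f <- (sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))) /
      (length(a) * length(b))
    2 * abs(f - 0.5)
  }, numeric(1)))
}

# Weir-Cockerham two-population F_ST estimator (ratio of averages),
# from per-population allele counts.
oracle_wc_fst <- function(geno, pop) {
  pops <- unique(pop)
  stopifnot(length(pops) == 2)
  n1 <- sum(pop == pops[1]); n2 <- sum(pop == pops[2])
  p1 <- colMeans(geno[pop == pops[1], , drop = FALSE]) / 2
  p2 <- colMeans(geno[pop == pops[2], , drop = FALSE]) / 2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) * s2 / r) / (2 * nbar - 1))
  b <- (nbar / (2 * nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) * s2 / r)
  sum(a) / sum(a + b)
}

# Tiny genotype table fixture on disk.
write_geno_fixture <- function(text, path = tempfile(fileext = ".csv")) {
  writeLines(text, path)
  path
}
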