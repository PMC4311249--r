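#' Pairwise distances between individuals
#'
#' Computes the symmetric, zero-diagonal matrix of pairwise dissimilarities
#' between row vectors — the adjacency of the complete weighted graph from
#' which the minimum spanning tree is extracted. Supported norms: `euclidean`
#' (L2) and `correlation` (1 - Pearson r, range \[0, 2\]).
#'
#' @param x a [genotype_matrix] or a plain numeric matrix (rows = samples).
#' @param norm `"euclidean"` or `"correlation"`.
#' @return A list of class `distance_matrix` with `values` (n x n matrix) and
#'   `ids`.
#' @export
pairwise_distances <- function(x, norm = c("euclidean", "correlation")) {
  norm <- match.arg(norm)
  m <- if (inherits(x, "genotype_matrix")) x$values else as.matrix(x)
  if (nrow(m) < 2) stop_ncmce("input", "need at least 2 individuals")
  ids <- rownames(m) %||% paste0("ind", seq_len(nrow(m)))
  if (norm == "euclidean") {
    d <- as.matrix(stats::dist(m, method = "euclidean"))
  } else {
    if (ncol(m) < 2) stop_ncmce("input", "correlation norm needs >= 2 columns")
    sds <- apply(m, 1, stats::sd)
    if (any(sds == 0)) {
      stop_ncmce("input", "constant rows under correlation norm: ",
                 paste(ids[sds == 0], collapse = ", "))
    }
    d <- 1 - stats::cor(t(m))
    diag(d) <- 0
  }
  if (!all(is.finite(d))) stop_ncmce("input", "non-finite distances")
  dimnames(d) <- list(ids, ids)
  structure(list(values = d, ids = ids), class = "distance_matrix")
}

distance_matrix <- function(values, ids = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values) || any(abs(values - t(values)) > 1e-12) ||
      any(diag(values) != 0) || !all(is.finite(values))) {
    stop_ncmce("input", "distance matrix must be square, symmetric, finite, zero-diagonal")
  }
  ids <- ids %||% rownames(values) %||% paste0("ind", seq_len(nrow(values)))
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, ids = ids), class = "distance_matrix")
}

#' Minimum spanning tree of a distance matrix
#'
#' Prim's algorithm on the dense matrix, O(n^2). Equal-weight alternatives are
#' resolved deterministically by preferring the lexicographically smallest
#' edge (i, j), i < j, so repeated runs and sample permutations give
#' reproducible trees.
#'
#' @param d a `distance_matrix` (from [pairwise_distances()]) or a plain
#'   symmetric matrix.
#' @return A list of class `spanning_tree` with `edges` (data frame `i`, `j`,
#'   `weight`, i < j), `n` and `ids`.
#' @export
minimum_spanning_tree <- function(d) {
  if (!inherits(d, "distance_matrix")) d <- distance_matrix(d)
  w <- d$values
  n <- nrow(w)
  if (n < 2) stop_ncmce("input", "need at least 2 nodes")
  in_tree <- logical(n)
  in_tree[1] <- TRUE
  best_w <- w[1, ]
  best_from <- rep(1L, n)
  ei <- ej <- integer(n - 1)
  ew <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    wmin <- min(best_w[cand])
    tied <- cand[best_w[cand] == wmin]
    pi <- pmin(best_from[tied], tied)
    pj <- pmax(best_from[tied], tied)
    pick <- order(pi, pj)[1]
    v <- tied[pick]
    ei[k] <- pi[pick]; ej[k] <- pj[pick]; ew[k] <- wmin
    in_tree[v] <- TRUE
    for (u in which(!in_tree)) {
      if (w[v, u] < best_w[u] ||
          (w[v, u] == best_w[u] &&
           (min(v, u) < min(best_from[u], u) ||
            (min(v, u) == min(best_from[u], u) &&
             max(v, u) < max(best_from[u], u))))) {
        best_w[u] <- w[v, u]
        best_from[u] <- v
      }
    }
  }
  structure(list(edges = data.frame(i = ei, j = ej, weight = ew), n = n,
                 ids = d$ids), class = "spanning_tree")
}

#' Minimum curvilinear kernel: all-pairs distances over the MST
#'
#' Re-measures the distance between every pair of individuals along the
#' unique path joining them in the spanning tree. The result is an additive
#' tree metric (it satisfies the four-point condition) that approximates
#' curvilinear (geodesic) distances along the data manifold, and is the
#' kernel decomposed by [ncmce_embed()]/[mce_embed()]. Computed by one graph
#' traversal per node, O(n^2) total.
#'
#' @param t a `spanning_tree` from [minimum_spanning_tree()].
#' @return A list of class `mc_kernel` with `values` (n x n symmetric matrix)
#'   and `ids`.
#' @export
mc_kernel <- function(t) {
  stopifnot(inherits(t, "spanning_tree"))
  n <- t$n
  edges <- t$edges
  if (nrow(edges) != n - 1) stop_ncmce("structure", "spanning tree must have n-1 edges")
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]; wt <- edges$weight[k]
    adj[[i]] <- rbind(adj[[i]], c(j, wt))
    adj[[j]] <- rbind(adj[[j]], c(i, wt))
  }
  if (any(vapply(adj, is.null, logical(1)))) {
    stop_ncmce("structure", "edge set does not span all nodes")
  }
  K <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist_s <- rep(NA_real_, n)
    dist_s[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      for (r in seq_len(nrow(nb))) {
        u <- nb[r, 1]
        if (is.na(dist_s[u])) {
          dist_s[u] <- dist_s[v] + nb[r, 2]
          queue <- c(queue, u)
        }
      }
    }
    if (anyNA(dist_s)) stop_ncmce("structure", "edge set is disconnected")
    K[s, ] <- dist_s
  }
  dimnames(K) <- list(t$ids, t$ids)
  structure(list(values = K, ids = t$ids), class = "mc_kernel")
}

# Shared SVD step for the (non-)centred kernels. The kernel is symmetric, so
# its singular value decomposition is obtained from the eigendecomposition
# K = Q L Q': singular values |L| in decreasing order, right singular vectors
# the corresponding eigenvectors. This is deterministic even when singular
# values are degenerate (where LAPACK's dgesdd may pick an arbitrary basis).
# Coordinates on dimension m are sqrt(S_m) * V[, m]; each dimension's sign is
# fixed so that its largest |coordinate| is positive.
kernel_svd_embed <- function(K, d, ids, method) {
  n <- nrow(K)
  if (d < 1 || d > n) stop_ncmce("dimension", "d must be in 1..n, got ", d)
  eg <- eigen(K, symmetric = TRUE)
  ord <- order(abs(eg$values), decreasing = TRUE)
  svals <- abs(eg$values)[ord]
  V <- eg$vectors[, ord, drop = FALSE]
  coords <- sweep(V[, seq_len(d), drop = FALSE], 2,
                  sqrt(svals[seq_len(d)]), `*`)
  for (m in seq_len(d)) {
    peak <- which.max(abs(coords[, m]))
    if (coords[peak, m] < 0) coords[, m] <- -coords[, m]
  }
  dimnames(coords) <- list(ids, paste0("Dim", seq_len(d)))
  structure(list(coords = coords, spectrum = svals[seq_len(d)],
                 method = method, ids = ids), class = "mc_embedding")
}

#' Non-centred minimum curvilinear embedding
#'
#' Applies the economy-size singular value decomposition directly to the
#' MC-kernel `K = U S V'` (no centring) and returns the coordinates
#' `sqrt(S_m) * V[, m]` for the leading `d` dimensions, in decreasing
#' singular-value order. For the non-centred kernel the first dimension
#' typically carries overall magnitude; group discrimination usually appears
#' on dimension 2.
#'
#' @param k an `mc_kernel` (or any symmetric non-negative matrix).
#' @param d number of embedding dimensions (`1 <= d <= n`).
#' @return A list of class `mc_embedding` with `coords` (n x d), `spectrum`
#'   (top d singular values, non-increasing), `method` and `ids`.
#' @export
ncmce_embed <- function(k, d = 2) {
  if (!inherits(k, "mc_kernel")) {
    k <- structure(list(values = as.matrix(k),
                        ids = rownames(k) %||% paste0("ind", seq_len(nrow(as.matrix(k))))),
                   class = "mc_kernel")
  }
  kernel_svd_embed(k$values, d, k$ids, "ncMCE")
}

#' Centred minimum curvilinear embedding
#'
#' The centred variant: the MC-kernel is double-centred with
#' `J = I - (1/n) 11'` (i.e. `J K J`), after which the SVD embedding proceeds
#' exactly as in [ncmce_embed()].
#'
#' @inheritParams ncmce_embed
#' @return A list of class `mc_embedding`; see [ncmce_embed()].
#' @export
mce_embed <- function(k, d = 2) {
  if (!inherits(k, "mc_kernel")) {
    k <- structure(list(values = as.matrix(k),
                        ids = rownames(k) %||% paste0("ind", seq_len(nrow(as.matrix(k))))),
                   class = "mc_kernel")
  }
  K <- k$values
  Kc <- sweep(K, 1, rowMeans(K))
  Kc <- sweep(Kc, 2, colMeans(Kc))
  kernel_svd_embed(Kc, d, k$ids, "MCE")
}

#' Principal component analysis baseline
#'
#' Column-mean-centres the matrix and projects it onto the right singular
#' vectors of the centred matrix, in order of decreasing explained variance.
#' The linear baseline against which the curvilinear embeddings are compared.
#'
#' @param x a [genotype_matrix] or plain numeric matrix (rows = samples).
#' @param d number of components, `d <= min(n - 1, n_cols)` recommended;
#'   values up to `min(n, n_cols)` are accepted.
#' @return A list of class `mc_embedding` with `coords` (PC scores),
#'   `spectrum` (per-component variances), `method = "PCA"` and `ids`.
#' @export
pca_embed <- function(x, d = 2) {
  m <- if (inherits(x, "genotype_matrix")) x$values else as.matrix(x)
  if (nrow(m) < 2) stop_ncmce("input", "need at least 2 rows")
  if (d < 1 || d > min(dim(m))) {
    stop_ncmce("dimension", "d must be in 1..min(n_rows, n_cols), got ", d)
  }
  ids <- rownames(m) %||% paste0("ind", seq_len(nrow(m)))
  mc <- sweep(m, 2, colMeans(m))
  sv <- svd(mc, nu = d, nv = 0)
  coords <- sweep(sv$u, 2, sv$d[seq_len(d)], `*`)
  for (j in seq_len(d)) {
    peak <- which.max(abs(coords[, j]))
    if (coords[peak, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(ids, paste0("Dim", seq_len(d)))
  structure(list(coords = coords,
                 spectrum = sv$d[seq_len(d)]^2 / (nrow(m) - 1),
                 method = "PCA", ids = ids), class = "mc_embedding")
}

#' @export
print.mc_embedding <- function(x, ...) {
  cat(sprintf("%s embedding: %d samples x %d dimensions\n", x$method,
              nrow(x$coords), ncol(x$coords)))
  cat("spectrum:", format(x$spectrum, digits = 4), "\n")
  invisible(x)
}

#' Full embedding pipeline
#'
#' For `ncMCE`/`MCE`: pairwise distances under the chosen norm, minimum
#' spanning tree, MC-kernel, then the (non-)centred SVD embedding. For `PCA`
#' the matrix is embedded directly and `norm` is ignored (with a message).
#'
#' @param g a [genotype_matrix] or plain numeric matrix.
#' @param method `"ncMCE"`, `"MCE"` or `"PCA"`.
#' @param norm distance norm for the curvilinear methods.
#' @param d number of embedding dimensions.
#' @return A list of class `mc_embedding`.
#' @export
embed_pipeline <- function(g, method = c("ncMCE", "MCE", "PCA"),
                           norm = c("euclidean", "correlation"), d = 2) {
  method <- match.arg(method)
  norm <- match.arg(norm)
  if (method == "PCA") {
    if (!missing(norm)) message("PCA ignores the norm argument")
    return(pca_embed(g, d))
  }
  k <- mc_kernel(minimum_spanning_tree(pairwise_distances(g, norm)))
  if (method == "ncMCE") ncmce_embed(k, d) else mce_embed(k, d)
}
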