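#' Population representative profiles
#'
#' Averages the SNP values of all individuals within each population to
#' produce one representative row per population, the input for the UPGMA
#' dendrograms. By default the matrix is mode-imputed first when it still
#' contains missing calls (value 3), since a numeric 3 would distort the
#' means.
#'
#' @param g a labelled [genotype_matrix].
#' @param impute_first impute missing calls (mode) before averaging; only
#'   applies to integer-coded matrices containing 3s.
#' @return A numeric matrix, populations x SNPs, rownames = population names
#'   in sorted order.
#' @export
population_representatives <- function(g, impute_first = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(g$labels)) stop_ncmce("labelling", "genotype matrix has no labels")
  if (impute_first && g$integer_coded && any(g$values == 3)) {
    g <- impute_missing(g, "mode")
  }
  pops <- sort(unique(g$labels))
  reps <- t(vapply(pops, function(p) {
    colMeans(g$values[g$labels == p, , drop = FALSE])
  }, numeric(ncol(g$values))))
  rownames(reps) <- pops
  reps
}

#' UPGMA hierarchical clustering
#'
#' Unweighted pair-group average linkage on a distance matrix: at each step
#' the two clusters at smallest average inter-cluster distance are merged at
#' a height equal to that distance, and distances to the merged cluster are
#' the size-weighted average of the members' distances (equivalently, the
#' unweighted average over all member pairs). Equal-distance candidates are
#' resolved by the lexicographically smallest pair of cluster names, a
#' cluster's name being its alphabetically first leaf. Heights are
#' non-decreasing, so the dendrogram is ultrametric.
#'
#' @param d a `distance_matrix` (e.g. from [pairwise_distances()] on
#'   [population_representatives()]) or a plain symmetric matrix with
#'   dimnames.
#' @return A list of class `linkage_tree` with `merges` (data frame `a`, `b`,
#'   `height`, `size`; `a`/`b` are hclust-style indices, negative for leaves,
#'   positive for earlier merges) and `leaf_names`.
#' @export
upgma <- function(d) {
  if (!inherits(d, "distance_matrix")) d <- distance_matrix(d)
  n <- length(d$ids)
  if (n < 2) stop_ncmce("input", "need at least 2 populations")
  dm <- d$values
  # active clusters: id (hclust convention), name (first leaf), size
  act_id <- -seq_len(n)
  act_name <- d$ids
  act_size <- rep(1L, n)
  merges <- data.frame(a = integer(n - 1), b = integer(n - 1),
                       height = numeric(n - 1), size = integer(n - 1))
  for (step in seq_len(n - 1)) {
    k <- length(act_id)
    best <- NULL
    for (p in seq_len(k - 1)) for (q in seq(p + 1, k)) {
      nm <- sort(c(act_name[p], act_name[q]))
      cand <- list(h = dm[p, q], nm1 = nm[1], nm2 = nm[2], p = p, q = q)
      if (is.null(best) || cand$h < best$h ||
          (cand$h == best$h && (cand$nm1 < best$nm1 ||
            (cand$nm1 == best$nm1 && cand$nm2 < best$nm2)))) {
        best <- cand
      }
    }
    p <- best$p; q <- best$q
    if (act_name[q] < act_name[p]) { tmp <- p; p <- q; q <- tmp }
    new_size <- act_size[p] + act_size[q]
    merges$a[step] <- act_id[p]
    merges$b[step] <- act_id[q]
    merges$height[step] <- best$h
    merges$size[step] <- new_size
    # UPGMA update: size-weighted mean of distances to the two merged clusters
    new_row <- (act_size[p] * dm[p, ] + act_size[q] * dm[q, ]) / new_size
    keep <- setdiff(seq_len(k), c(p, q))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], new_row[keep]),
                c(new_row[keep], 0))
    act_id <- c(act_id[keep], step)
    act_name <- c(act_name[keep], min(best$nm1, best$nm2))
    act_size <- c(act_size[keep], new_size)
  }
  structure(list(merges = merges, leaf_names = d$ids), class = "linkage_tree")
}

#' Cophenetic distance matrix of a linkage tree
#'
#' The height at which each pair of leaves is first joined; for a UPGMA tree
#' this matrix is ultrametric.
#'
#' @param t a `linkage_tree`.
#' @return Symmetric numeric matrix with leaf names as dimnames.
#' @export
cophenetic_matrix <- function(t) {
  stopifnot(inherits(t, "linkage_tree"))
  n <- length(t$leaf_names)
  members <- function(id) {
    if (id < 0) return(-id)
    c(members(t$merges$a[id]), members(t$merges$b[id]))
  }
  cm <- matrix(0, n, n, dimnames = list(t$leaf_names, t$leaf_names))
  for (step in seq_len(n - 1)) {
    la <- members(t$merges$a[step])
    lb <- members(t$merges$b[step])
    cm[la, lb] <- t$merges$height[step]
    cm[lb, la] <- t$merges$height[step]
  }
  cm
}

quote_newick <- function(x) {
  ifelse(grepl("[][(): ;,']", x), paste0("'", gsub("'", "''", x), "'"), x)
}

#' Export a linkage tree as a Newick string
#'
#' Branch lengths follow the ultrametric convention: a node at merge height h
#' places its children at branch length `h/2 - child_height/2`, so every leaf
#' sits at distance `root_height / 2` from the root. Names containing spaces
#' or Newick metacharacters are single-quoted.
#'
#' @param t a `linkage_tree`.
#' @param digits significant digits for branch lengths.
#' @return A Newick string terminated by `";"`.
#' @export
to_newick <- function(t, digits = 10) {
  stopifnot(inherits(t, "linkage_tree"))
  node_str <- function(id, parent_h) {
    if (id < 0) {
      h <- 0
      lab <- quote_newick(t$leaf_names[-id])
    } else {
      h <- t$merges$height[id]
      lab <- paste0("(", node_str(t$merges$a[id], h), ",",
                    node_str(t$merges$b[id], h), ")")
    }
    paste0(lab, ":", format((parent_h - h) / 2, digits = digits, trim = TRUE))
  }
  root <- nrow(t$merges)
  h <- t$merges$height[root]
  paste0("(", node_str(t$merges$a[root], h), ",",
         node_str(t$merges$b[root], h), ");")
}

#' UPGMA population tree from a labelled genotype matrix
#'
#' Convenience wrapper: mode-imputed population representatives, Euclidean
#' distances between them, UPGMA linkage.
#'
#' @param g a labelled [genotype_matrix].
#' @param impute_first see [population_representatives()].
#' @return A `linkage_tree`.
#' @export
population_tree <- function(g, impute_first = TRUE) {
  reps <- population_representatives(g, impute_first = impute_first)
  upgma(pairwise_distances(reps, "euclidean"))
}
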