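#' Concordance score of labelled groups along a 1-D projection
#'
#' Quantifies how cleanly labelled groups occupy disjoint intervals of a
#' one-dimensional projection. For every unordered pair of groups (Pi, Pj)
#' the fraction of cross pairs ordered one way is
#' `f_ij = (#\{x in Pi, y in Pj : p(x) > p(y)\} + ties / 2) / (|Pi| |Pj|)`
#' (ties contribute one half, the rank-statistic convention), the pair score
#' is `2 |f_ij - 1/2|`, and the C-score is the unweighted mean of the pair
#' scores. It equals 1 when groups appear one after the other with no mixing
#' (perfect blocked ordering), and 0 for an exactly balanced interleave (no
#' structure). Invariant under strictly increasing transforms, reflection of
#' the projection, and group relabelling.
#'
#' @param projection numeric vector: 1-D coordinates of the individuals.
#' @param labels vector of group names, same length (at least two distinct
#'   non-empty groups).
#' @return A number in `[0, 1]`.
#' @export
cscore <- function(projection, labels) {
  if (length(projection) != length(labels)) {
    stop_ncmce("input", "projection and labels differ in length")
  }
  if (anyNA(projection) || anyNA(labels)) {
    stop_ncmce("input", "projection/labels contain NA")
  }
  groups <- split(as.numeric(projection), as.character(labels))
  if (length(groups) < 2) {
    stop_ncmce("grouping", "need at least two groups, got ",
               paste(names(groups), collapse = ", "))
  }
  prs <- utils::combn(names(groups), 2, simplify = FALSE)
  s <- vapply(prs, function(pr) {
    a <- groups[[pr[1]]]
    b <- groups[[pr[2]]]
    r <- rank(c(a, b))
    u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
    f <- u / (length(a) * length(b))
    2 * abs(f - 0.5)
  }, numeric(1))
  mean(s)
}

#' C-score over several embedding dimensions
#'
#' Computes the C-score of each requested embedding dimension and reports the
#' best, the usual figure of merit when inspecting the first two dimensions
#' of an ncMCE or PCA projection.
#'
#' @param e an `mc_embedding` (or a coordinate matrix).
#' @param labels group names, one per sample, or `NULL` to use the labels of
#'   a `genotype_matrix`-derived embedding.
#' @param dims integer vector of dimension indices to score (default: all).
#' @return A list of class `cscore_result` with `per_dimension` (named by
#'   dimension), `best`, `best_dim` and `dims_considered`.
#' @export
best_cscore <- function(e, labels, dims = NULL) {
  coords <- if (inherits(e, "mc_embedding")) e$coords else as.matrix(e)
  dims <- dims %||% seq_len(ncol(coords))
  if (any(dims < 1 | dims > ncol(coords))) {
    stop_ncmce("dimension", "dims out of range 1..", ncol(coords))
  }
  per <- vapply(dims, function(m) cscore(coords[, m], labels), numeric(1))
  names(per) <- paste0("Dim", dims)
  structure(list(per_dimension = per, best = max(per),
                 best_dim = dims[which.max(per)], dims_considered = dims),
            class = "cscore_result")
}

#' @export
print.cscore_result <- function(x, ...) {
  cat("C-score per dimension:\n")
  print(round(x$per_dimension, 4))
  cat(sprintf("best: %.4f (Dim%d)\n", x$best, x$best_dim))
  invisible(x)
}
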