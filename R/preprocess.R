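#' Fraction of missing genotype calls
#'
#' @param g an integer-coded [genotype_matrix] (missing calls coded 3).
#' @return The fraction of cells equal to 3, in `[0, 1]`.
#' @export
missing_rate <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!g$integer_coded) {
    stop_ncmce("state", "missing_rate needs an integer-coded matrix")
  }
  mean(g$values == 3)
}

# Mode of a numeric vector; ties resolved to the smallest value, which in
# genotype coding favours the wild-type allele.
stat_mode <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)][1])
}

#' Impute missing genotypes per SNP
#'
#' Replaces every missing call (value 3) in a column by the mode, mean or
#' median of that column's observed values. Observed cells are never altered,
#' and the operation is idempotent. Mode ties are broken toward the smallest
#' genotype value. Mean/median imputation may introduce fractional values, in
#' which case the result is no longer integer coded.
#'
#' @param g an integer-coded [genotype_matrix].
#' @param strategy one of `"mode"`, `"mean"`, `"median"`.
#' @return A [genotype_matrix] containing no 3s.
#' @export
impute_missing <- function(g, strategy = c("mode", "mean", "median")) {
  stopifnot(inherits(g, "genotype_matrix"))
  strategy <- match.arg(strategy)
  if (!g$integer_coded) {
    stop_ncmce("state", "impute_missing needs an integer-coded matrix")
  }
  values <- g$values
  fill <- switch(strategy, mode = stat_mode, mean = mean, median = stats::median)
  miss_cols <- which(colSums(values == 3) > 0)
  for (j in miss_cols) {
    col <- values[, j]
    obs <- col[col != 3]
    if (length(obs) == 0) {
      stop_ncmce("imputation", "SNP entirely missing: ", g$snp_ids[j])
    }
    values[col == 3, j] <- fill(obs)
  }
  out <- genotype_matrix(values, g$sample_ids, g$snp_ids)
  out$labels <- g$labels
  # mean/median of {0,1,2} can coincide with the integer coding; an imputed
  # matrix is reported as non-integer-coded regardless, since 3 no longer
  # means "missing" downstream.
  out$integer_coded <- strategy == "mode" && out$integer_coded
  out
}

# Two-sided rank-sum p-value by exhaustive enumeration of all C(n, na)
# assignments of the pooled midranks to group A. Exact under ties.
ranksum_exact <- function(a, b) {
  na <- length(a)
  r2 <- 2 * rank(c(a, b))                 # doubled midranks are integers
  mu <- na * (length(r2) + 1)             # mean of the doubled rank sum
  w_obs <- sum(r2[seq_len(na)])
  dev <- abs(w_obs - mu)
  sets <- utils::combn(length(r2), na)
  w_all <- colSums(matrix(r2[sets], nrow = na))
  mean(abs(w_all - mu) >= dev)
}

#' Per-SNP Mann-Whitney rank-sum tests between two groups
#'
#' Treats each SNP column as two samples (group A vs group B) and computes a
#' two-sided Mann-Whitney/Wilcoxon rank-sum p-value per SNP. Values are used
#' as given, so on a raw matrix the missing code 3 participates as a numeric
#' value — the intended behaviour when testing which SNPs drive a separation
#' observed on unimputed data. P-values are exact (full enumeration, midrank
#' ties) when `min(|A|, |B|) <= 8`, otherwise a normal approximation with tie
#' and continuity correction is used. A SNP constant across both groups gets
#' p = 1 by convention.
#'
#' @param g a [genotype_matrix].
#' @param group_a,group_b disjoint, non-empty character vectors of sample ids.
#' @return A data frame with columns `snp_index`, `snp_id`, `p_value`.
#' @export
mannwhitney_snps <- function(g, group_a, group_b) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (length(intersect(group_a, group_b)) > 0) {
    stop_ncmce("grouping", "groups overlap: ",
               paste(intersect(group_a, group_b), collapse = ", "))
  }
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop_ncmce("grouping", "both groups must be non-empty")
  }
  unknown <- setdiff(c(group_a, group_b), g$sample_ids)
  if (length(unknown) > 0) {
    stop_ncmce("grouping", "unknown sample ids: ", paste(unknown, collapse = ", "))
  }
  ia <- match(group_a, g$sample_ids)
  ib <- match(group_b, g$sample_ids)
  exact <- min(length(ia), length(ib)) <= 8
  p <- vapply(seq_len(ncol(g$values)), function(j) {
    a <- g$values[ia, j]
    b <- g$values[ib, j]
    if (max(c(a, b)) == min(c(a, b))) return(1.0)   # constant column
    if (exact) {
      ranksum_exact(a, b)
    } else {
      min(1, stats::wilcox.test(a, b, alternative = "two.sided",
                                exact = FALSE, correct = TRUE)$p.value)
    }
  }, numeric(1))
  data.frame(snp_index = seq_len(ncol(g$values)), snp_id = g$snp_ids,
             p_value = p, stringsAsFactors = FALSE)
}

#' Select significant SNPs by p-value threshold
#'
#' Selection is boundary-inclusive (`p <= alpha`). With
#' `correction = "benjamini_hochberg"` the threshold is applied to
#' Benjamini-Hochberg step-up adjusted p-values instead.
#'
#' @param results data frame from [mannwhitney_snps()] (columns `snp_index`,
#'   `p_value`).
#' @param alpha significance level in (0, 1); the rank-sum screen in the
#'   source analyses used 0.01.
#' @param correction `"none"` or `"benjamini_hochberg"`.
#' @return Integer vector of selected `snp_index` values sorted by ascending
#'   p-value (ties by index).
#' @export
select_significant <- function(results, alpha = 0.01,
                               correction = c("none", "benjamini_hochberg")) {
  correction <- match.arg(correction)
  stopifnot(alpha > 0, alpha < 1)
  if (NROW(results) == 0) return(integer(0))
  p <- results$p_value
  crit <- if (correction == "benjamini_hochberg") {
    stats::p.adjust(p, method = "BH")
  } else p
  keep <- which(crit <= alpha)
  keep <- keep[order(p[keep], results$snp_index[keep])]
  as.integer(results$snp_index[keep])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Convenience wrapper around `stats::p.adjust(method = "BH")` returning the
#' step-up adjusted values in input order.
#'
#' @param p numeric vector of p-values.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Log-transform a genotype matrix for heat-map display
#'
#' Elementwise `log10(1 + value)`; with the 0/1/2/3 coding this maps missing
#' calls (3) to `log10(4)` like any other value, as used for significant-SNP
#' heat maps.
#'
#' @param g a [genotype_matrix] (values must be non-negative).
#' @return A numeric matrix of the same shape with dimnames preserved.
#' @export
heatmap_transform <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (any(g$values < 0)) stop_ncmce("domain", "negative genotype values")
  log10(1 + g$values)
}
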