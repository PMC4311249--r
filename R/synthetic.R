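#' Two interleaved curved clusters in 3-D
#'
#' Generates the didactic dataset used to contrast linear and curvilinear
#' embeddings: two nested cylindrical-arc sheets in three dimensions. Cluster
#' `c` (c = 0, 1) is sampled as
#' `(u, r_c sin(theta), r_c (1 - stretch) cos(theta) + c * gap)` with `u`
#' uniform along the sheet, `theta` uniform over an arc, plus isotropic
#' Gaussian noise. At `stretch = 0` the sheets are fully curved and nested —
#' no linear 1-D projection separates them — while `stretch = 1` collapses
#' the curvature so each sheet is an exact plane (up to noise) and the
#' clusters become linearly separable along the third axis. The default arc
#' extent of `3 * pi / 4` (rather than a full half-circle) keeps the outer
#' sheet's free end away from the inner sheet at intermediate stretch, so
#' with the default inner radius 1, outer radius 2, `gap = 1.2` and sheet
#' depth 0.5 the minimum inter-sheet distance stays well above the
#' within-sheet nearest-neighbour spacing at every stretch level and the
#' minimum spanning tree bridges the sheets only once.
#'
#' @param n_per_cluster points per cluster.
#' @param stretch curvature-collapsing factor in `[0, 1]`.
#' @param noise_sd standard deviation of isotropic Gaussian noise.
#' @param gap vertical offset of the outer sheet (> 0).
#' @param radii radii of the two arcs (inner, outer).
#' @param depth extent of the sheets along the first (extrusion) axis.
#' @param arc angular extent of the arcs, in radians.
#' @param seed RNG seed; same seed, same output.
#' @return A list with `points` (2n x 3 matrix) and `labels` (factor
#'   `"C1"`/`"C2"`).
#' @export
make_curved_clusters <- function(n_per_cluster = 100, stretch = 0,
                                 noise_sd = 0.05, gap = 1.2,
                                 radii = c(1, 2), depth = 0.5,
                                 arc = 3 * pi / 4, seed = 0) {
  if (stretch < 0 || stretch > 1) {
    stop_ncmce("domain", "stretch must be in [0, 1], got ", stretch)
  }
  if (gap <= 0) stop_ncmce("domain", "gap must be > 0")
  with_seed(seed, {
    n <- n_per_cluster
    pts <- lapply(0:1, function(cl) {
      u <- stats::runif(n, 0, depth)
      theta <- stats::runif(n, 0, arc)
      r <- radii[cl + 1]
      cbind(u,
            r * sin(theta),
            r * (1 - stretch) * cos(theta) + cl * gap) +
        matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
    })
    points <- rbind(pts[[1]], pts[[2]])
    rownames(points) <- paste0("pt", seq_len(2 * n))
    colnames(points) <- c("x", "y", "z")
    list(points = points,
         labels = factor(rep(c("C1", "C2"), each = n)))
  })
}

# Recursive Balding-Nichols drift step: child allele frequency is Beta
# distributed around the parent frequency with concentration (1 - F) / F.
bn_drift <- function(p, f) {
  if (f < 1e-12) return(p)
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  stats::rbeta(length(p), a, b)
}

#' Define a population-tree node for the genotype simulator
#'
#' A leaf (`pop_leaf`) names a population; an internal node (`pop_node`)
#' groups children. `f` is the Balding-Nichols drift parameter of the branch
#' leading to the node from its parent, in `(0, 1)` (approximately the F_ST
#' accumulated along that branch); it is ignored on the root.
#'
#' @param name leaf population name.
#' @param children list of child nodes.
#' @param f per-branch drift parameter.
#' @return A tree-node list understood by [simulate_genotypes()].
#' @export
pop_leaf <- function(name, f) list(name = name, f = f)

#' @rdname pop_leaf
#' @export
pop_node <- function(children, f = 0) list(children = children, f = f)

collect_leaves <- function(node) {
  if (!is.null(node$name)) return(node$name)
  unlist(lapply(node$children, collect_leaves))
}

validate_tree <- function(node, is_root = TRUE) {
  if (!is_root && (node$f < 0 || node$f >= 1)) {
    stop_ncmce("domain", "branch drift F must be in [0, 1), got ", node$f)
  }
  if (is.null(node$name)) lapply(node$children, validate_tree, is_root = FALSE)
  invisible(TRUE)
}

#' Simulate tree-structured multi-population genotypes
#'
#' Balding-Nichols model: for each SNP an ancestral allele frequency is drawn
#' uniformly from `ancestral_freq_range`; along every branch with drift
#' parameter F the child frequency is Beta(p(1-F)/F, (1-p)(1-F)/F)
#' distributed around the parent frequency p; each individual's genotype is
#' Binomial(2, leaf frequency). Leaf frequencies are clipped to
#' `[1e-3, 1 - 1e-3]` so no SNP is fixed. Population labels are set to the
#' leaf names.
#'
#' @param tree a population topology built from [pop_node()]/[pop_leaf()],
#'   or, for the common two-population case, a numeric drift value `F` (the
#'   two populations "P1", "P2" then each sit on a branch of drift `F/2`, so
#'   their pairwise differentiation is approximately `F`).
#' @param n_ind_per_pop individuals per leaf population.
#' @param n_snps number of SNPs.
#' @param ancestral_freq_range range of the uniform ancestral frequency.
#' @param seed RNG seed.
#' @return A labelled, integer-coded [genotype_matrix] with values in
#'   \{0, 1, 2\}.
#' @export
simulate_genotypes <- function(tree, n_ind_per_pop = 50, n_snps = 1000,
                               ancestral_freq_range = c(0.1, 0.9), seed = 0) {
  if (is.numeric(tree) && length(tree) == 1) {
    tree <- pop_node(list(pop_leaf("P1", tree / 2), pop_leaf("P2", tree / 2)))
  }
  validate_tree(tree)
  leaves <- collect_leaves(tree)
  if (anyDuplicated(leaves)) stop_ncmce("domain", "duplicate leaf names")
  with_seed(seed, {
    p_anc <- stats::runif(n_snps, ancestral_freq_range[1],
                          ancestral_freq_range[2])
    leaf_freq <- list()
    walk <- function(node, p) {
      p_here <- bn_drift(p, node$f)
      if (!is.null(node$name)) {
        leaf_freq[[node$name]] <<- pmin(pmax(p_here, 1e-3), 1 - 1e-3)
      } else {
        for (ch in node$children) walk(ch, p_here)
      }
    }
    tree$f <- 0
    walk(tree, p_anc)
    values <- do.call(rbind, lapply(leaves, function(lf) {
      matrix(stats::rbinom(n_ind_per_pop * n_snps, 2,
                           rep(leaf_freq[[lf]], each = n_ind_per_pop)),
             nrow = n_ind_per_pop)
    }))
    ids <- paste0(rep(leaves, each = n_ind_per_pop), "_",
                  rep(seq_len(n_ind_per_pop), length(leaves)))
    labels <- stats::setNames(rep(leaves, each = n_ind_per_pop), ids)
    genotype_matrix(values, sample_ids = ids,
                    snp_ids = paste0("snp", seq_len(n_snps)), labels = labels)
  })
}

#' Simulate two groups with a subset of differentiated SNPs
#'
#' Companion generator for significant-SNP selection experiments: two groups
#' share allele frequencies at the null SNPs, while at `n_diff` randomly
#' placed truly differentiated SNPs the group frequencies are pushed apart
#' symmetrically by a contrast drawn uniformly from `contrast_range`
#' (guaranteeing a real frequency difference at every differentiated SNP,
#' unlike symmetric drift, under which the two groups can wander to the same
#' frequency).
#'
#' @param n_ind_per_pop individuals per group.
#' @param n_null,n_diff numbers of undifferentiated and differentiated SNPs.
#' @param contrast_range range of the absolute allele-frequency difference at
#'   differentiated SNPs.
#' @param ancestral_freq_range as in [simulate_genotypes()].
#' @param seed RNG seed.
#' @return A list with `genotypes` (labelled [genotype_matrix]) and
#'   `diff_snps` (integer indices of the truly differentiated SNPs).
#' @export
simulate_two_group_snps <- function(n_ind_per_pop = 100, n_null = 4800,
                                    n_diff = 200,
                                    contrast_range = c(0.2, 0.6),
                                    ancestral_freq_range = c(0.1, 0.9),
                                    seed = 0) {
  with_seed(seed, {
    n_snps <- n_null + n_diff
    diff_idx <- sort(sample.int(n_snps, n_diff))
    p_anc <- stats::runif(n_snps, ancestral_freq_range[1],
                          ancestral_freq_range[2])
    delta <- stats::runif(n_diff, contrast_range[1], contrast_range[2])
    freq <- list(A = p_anc, B = p_anc)
    freq$A[diff_idx] <- p_anc[diff_idx] + delta / 2
    freq$B[diff_idx] <- p_anc[diff_idx] - delta / 2
    for (gp in c("A", "B")) {
      freq[[gp]] <- pmin(pmax(freq[[gp]], 1e-3), 1 - 1e-3)
    }
    values <- do.call(rbind, lapply(c("A", "B"), function(gp) {
      matrix(stats::rbinom(n_ind_per_pop * n_snps, 2,
                           rep(freq[[gp]], each = n_ind_per_pop)),
             nrow = n_ind_per_pop)
    }))
    ids <- paste0(rep(c("A", "B"), each = n_ind_per_pop), "_",
                  rep(seq_len(n_ind_per_pop), 2))
    g <- genotype_matrix(values, sample_ids = ids,
                         snp_ids = paste0("snp", seq_len(n_snps)),
                         labels = stats::setNames(rep(c("A", "B"),
                                                      each = n_ind_per_pop), ids))
    list(genotypes = g, diff_snps = diff_idx)
  })
}

#' Inject missing calls into a genotype matrix
#'
#' Sets cells to the missing code 3. `mode = "mcar"` masks every cell
#' independently with probability `rate`. `mode = "group_biased"` mimics
#' platform-style artefacts: cells of samples in `biased_groups` are masked
#' with probability `1.6 * rate` and all other cells with `0.4 * rate` (a 4x
#' contrast whose average over a balanced design equals `rate`), using
#' independent per-SNP Bernoulli masks within each group.
#'
#' @param g an integer-coded [genotype_matrix] with values in \{0, 1, 2\}.
#' @param rate target overall missing fraction in `[0, 1)`.
#' @param mode `"mcar"` or `"group_biased"`.
#' @param biased_groups character vector of population labels (or sample ids)
#'   designating the high-missingness group; required for `group_biased`.
#' @param seed RNG seed.
#' @return A [genotype_matrix] with missing calls injected.
#' @export
inject_missing <- function(g, rate, mode = c("mcar", "group_biased"),
                           biased_groups = NULL, seed = 0) {
  stopifnot(inherits(g, "genotype_matrix"))
  mode <- match.arg(mode)
  if (rate < 0 || rate >= 1) stop_ncmce("domain", "rate must be in [0, 1)")
  if (rate == 0) return(g)
  values <- g$values
  with_seed(seed, {
    if (mode == "mcar") {
      mask <- matrix(stats::runif(length(values)) < rate,
                     nrow(values), ncol(values))
    } else {
      if (is.null(biased_groups)) {
        stop_ncmce("config", "group_biased mode requires biased_groups")
      }
      in_biased <- g$sample_ids %in% biased_groups
      if (!any(in_biased) && !is.null(g$labels)) {
        in_biased <- g$labels %in% biased_groups
      }
      if (!any(in_biased) || all(in_biased)) {
        stop_ncmce("config", "biased_groups must designate a proper subset of samples")
      }
      cell_rate <- ifelse(in_biased, 1.6 * rate, 0.4 * rate)
      mask <- matrix(stats::runif(length(values)), nrow(values), ncol(values)) <
        cell_rate
    }
    values[mask] <- 3
  })
  out <- genotype_matrix(values, g$sample_ids, g$snp_ids)
  out$labels <- g$labels
  out
}
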