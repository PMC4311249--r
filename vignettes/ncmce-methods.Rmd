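---
title: "Minimum curvilinear embedding for population structure: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum curvilinear embedding for population structure: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncmce)
```

## The model

ncMCE rests on the *minimum curvilinearity* principle: nonlinear
(curvilinear) distances between samples can be estimated as path distances
over the minimum spanning tree (MST) of the sample-to-sample distance graph.
The pipeline is

1. pairwise distances `A` between individuals (rows of the genotype or
   coordinate matrix) under a chosen norm — Euclidean by default, or
   `1 - Pearson r` (range [0, 2]) for the correlation norm;
2. the MST `T` of the complete graph weighted by `A`;
3. the MC-kernel `D`: all-pairs path distances over `T`. `D` is an additive
   tree metric — it satisfies the four-point condition, and dominates the
   input distances whenever those satisfy the triangle inequality (both
   properties are asserted over random instances in the test suite);
4. the singular value decomposition `D = U S V'`; sample `j`'s coordinate on
   embedding dimension `k` is `sqrt(S_k) * V[j, k]`, dimensions ordered by
   decreasing singular value.

MCE additionally double-centres the kernel (`J D J`, `J = I - (1/n) 11'`)
before step 4; ncMCE omits the centring. Because the non-centred kernel has
all-positive entries, its leading singular vector is nearly constant
(Perron–Frobenius): dimension 1 mostly encodes overall magnitude, and group
discrimination typically appears on dimension 2. All evaluation therefore
considers dimensions 1 *and* 2 and takes the better one.

The MST is what gives the method its robustness and its character: it is a
greedy summary of the local neighbourhood structure, so a curved sheet of
points is traversed *along* the sheet, and two sheets connected by a single
long bridge edge become two well-separated blocks of the tree metric. It is
also what ties the embedding to phylogeny — the kernel is itself a tree
metric, so hierarchically structured populations embed in their
hierarchical order.

The PCA baseline is the usual one: column-mean-centre the matrix, project
onto the right singular vectors, report per-component variances as the
spectrum.

## The C-score

Separability of labelled groups along one embedding dimension is measured
by a concordance score. For each unordered pair of groups \((P_i, P_j)\),

\[ f_{ij} = \frac{\#\{x \in P_i, y \in P_j : p(x) > p(y)\} + \tfrac12 \#\text{ties}}{|P_i|\,|P_j|}, \qquad
   s_{ij} = 2\,|f_{ij} - \tfrac12|, \]

and the C-score is the unweighted mean of \(s_{ij}\) over all group pairs.
\(f_{ij}\) is the two-sample Mann–Whitney exceedance probability, so the
score is invariant under any strictly increasing transform of the
projection, under reflection, and under group relabelling. Any arrangement
with contiguous, non-overlapping group blocks scores exactly 1; an exactly
balanced interleave scores 0.

Two conventions are fixed here deliberately: ties contribute one half (the
rank-statistic convention), and multi-group aggregation is the unweighted
mean over pairs rather than a size-weighted mean, so a small population
separating badly is not masked by two large ones separating well.

## Preprocessing

*Genotype coding.* 0 homozygous wild-type, 1 heterozygous, 2 homozygous
variant, 3 missing. Matrices read from delimited tables or VCF (GT
subfield; multiallelic records skipped) carry an `integer_coded` flag.

*Imputation.* Missing calls are replaced per SNP by the mode, mean or
median of that SNP's observed values. Mode ties resolve to the smallest
genotype value (deterministic, and biased toward the wild-type allele, the
most frequent state in typical panels). Mean/median imputation keeps
fractional values — the matrix feeds a numeric embedding, so rounding would
only discard information. Imputation is idempotent and never touches
observed cells.

*Rank-sum SNP selection.* Each SNP column is compared between two groups
with a two-sided Mann–Whitney test. When `min(|A|, |B|) <= 8` the p-value
is exact — full enumeration of all \(\binom{n}{|A|}\) assignments of the
pooled midranks (doubled to integers, so the enumeration is free of
floating-point ties) — otherwise the normal approximation with tie and
continuity correction is used. Columns constant across both groups get
p = 1 by convention. Tests run on the *raw* matrix, with 3 participating as
a numeric value: the screen is meant to explain a separation observed on
unimputed data, so the missingness pattern is part of the signal being
tested. Selection keeps SNPs with p ≤ α (boundary inclusive, α = 0.01 by
default), ordered by p; Benjamini–Hochberg adjustment is available at the
same α for a more stringent list. The heat-map transform is elementwise
`log10(1 + value)`, applied uniformly — including to the missing code 3.

## Population trees

Population representatives are per-SNP means over each population's
individuals, computed after mode imputation by default (a literal 3 would
distort the means; the raw behaviour is available via `impute_first =
FALSE`). Representatives are clustered by UPGMA on Euclidean distances:
merge the two clusters at the smallest average inter-cluster distance, at a
height equal to that distance. Merge ties resolve to the lexicographically
smallest pair of cluster names (a cluster is named by its alphabetically
first leaf), so the linkage is deterministic. Newick export halves the merge
heights so leaves sit at `root height / 2` — the ultrametric convention —
and quotes names containing metacharacters.

## Synthetic generators

The generators define the study conditions under which the package's
claims are tested; they are first-class, tested code.

*Curved clusters.* Two nested cylindrical-arc sheets in 3-D; cluster
\(c \in \{0, 1\}\) is sampled as
\((u,\; r_c \sin\theta,\; r_c (1 - \text{stretch}) \cos\theta + c \cdot \text{gap})\)
plus isotropic Gaussian noise, with `u` uniform over the sheet depth and
\(\theta\) uniform over an arc. `stretch` interpolates from full curvature
(0) to exact planes (1). Defaults: 100 points per cluster, radii (1, 2),
arc \(3\pi/4\), gap 1.2, depth 0.5, noise SD 0.05. The geometry was chosen
once so that three qualitative behaviours hold simultaneously:

- at stretch 0 the sheets are nested and no linear 1-D projection separates
  them (PCA best C-score over dimensions 1–2 stays well below 0.9), while
  the MST bridges the sheets exactly once and ncMCE separates them
  perfectly on dimension 2;
- at stretch 1 the sheets are parallel planes offset by `gap`, and PCA
  recovers the separation (best C-score ≥ 0.99);
- at every intermediate stretch the inter-sheet clearance stays well above
  the within-sheet nearest-neighbour spacing. This is why the arc stops at
  \(3\pi/4\) rather than a half circle: the outer sheet's free end would
  otherwise sweep through the inner sheet when the curvature scale
  \((1-\text{stretch})\) passes the gap, creating spurious MST bridges. The
  restriction keeps the outer arc's end at \(y = 2\sin(3\pi/4) \approx 1.41\),
  clear of the inner sheet (\(y \le 1\)) at every stretch level.

The invariant "minimum inter-sheet distance exceeds the 99th percentile of
within-sheet nearest-neighbour distances" is asserted in the tests at the
default configuration.

*Genotypes.* The Balding–Nichols drift model: per SNP an ancestral
frequency \(p \sim U(0.1, 0.9)\); along each branch with drift parameter
\(F\), the child frequency is
\(\text{Beta}\big(p\,(1-F)/F,\; (1-p)(1-F)/F\big)\); individuals draw
genotypes \(\text{Binomial}(2, p_{\text{leaf}})\). Leaf frequencies are
clipped to \([10^{-3}, 1-10^{-3}]\) so no SNP is fixed. A scalar shorthand
`simulate_genotypes(F, ...)` places two populations on branches of drift
F/2 each, giving pairwise differentiation ≈ F; the test suite verifies
Weir–Cockerham F_ST ∈ [0.08, 0.12] at F = 0.1 over 50,000 SNPs. The model
is closed-form and F_ST-parameterised — sufficient for structure-detection
scenarios; it deliberately omits linkage, coalescent genealogies,
admixture and ascertainment bias.

For SNP-selection experiments, `simulate_two_group_snps()` gives two groups
identical frequencies at null SNPs and a guaranteed frequency contrast
(uniform on [0.2, 0.6], split symmetrically) at the differentiated SNPs.
Symmetric drift was rejected for this purpose: under drift, both groups can
wander to the same frequency, so a fixed fraction of nominally
"differentiated" SNPs carries no signal and no recovery target can be
stated cleanly.

*Missingness.* `inject_missing()` sets cells to 3 either completely at
random or in a group-biased way: cells of designated samples are masked at
1.6× the target rate and all others at 0.4× (a 4× contrast averaging to the
target on a balanced design; the rates are scaled so the realized overall
rate matches the target). Masks are independent Bernoulli per cell within
each group.

### What the missingness generator does and does not show

With two populations at F = 0.02, 20,000 SNPs, and group-biased missingness
at 0.73% overall (the regime exercised in the acceptance tests): ncMCE on
the raw matrix and PCA on the mode-imputed matrix both separate the
populations perfectly. What this generator does **not** reproduce is the
degradation of PCA by the raw missing values. A cell-level Bernoulli mask
at 0.73% adds roughly 1% to the total variance and a between-group mean
shift more than an order of magnitude below the genetic signal at F = 0.02,
so PCA on the raw matrix is indistinguishable from PCA on the imputed one
at any problem size — the imputation-rescue phenomenon reported on real
cohorts requires *platform-structured* missingness (entire SNP panels
absent for one batch of samples), which concentrates the perturbation into
a few high-variance directions. Conversely, when the biased missingness is
aligned with the populations themselves, it is the *tree metric* that
suffers: high-missingness individuals are pushed apart from each other
(each contributes its own masked cells to every within-group distance),
cross-group pairs become relatively closer, and the MST mixes the groups
while PCA is unaffected. Passing tests therefore demonstrate robustness of
ncMCE to random and batch-style missingness at realistic rates, not a
general advantage of ncMCE over PCA on poorly pre-processed data.

## Numerical choices

- *MST*: Prim's algorithm on the dense matrix, O(n²); equal-weight
  alternatives resolve to the lexicographically smallest edge (i, j), so
  trees are reproducible and permutation-equivariant. All-pairs tree
  distances by one traversal per node, O(n²) total.
- *Kernel SVD*: the kernel is symmetric, so its SVD is computed from the
  eigendecomposition (singular values = |eigenvalues|, vectors =
  eigenvectors). This is equivalent to the economy-size SVD but
  deterministic under degenerate singular values, where LAPACK's SVD may
  return an arbitrary basis of the degenerate subspace.
- *Sign convention*: each embedding dimension is flipped so its largest
  |coordinate| is positive — plots and tests are reproducible; geometry is
  unchanged.
- *Exact rank-sum enumeration* switches to the normal approximation above
  group size 8 (≈ 12,870 enumerated assignments at the 8 vs 8 boundary).
- *Degenerate inputs* fail loudly with typed errors: constant rows under
  the correlation norm, all-missing SNP columns, single-group label sets,
  non-finite distances, out-of-range embedding dimensions.

## Problem sizes in the test suite

The acceptance-style tests run the curved-cluster contrast at 100 points
per cluster, the stretch sweep at 150 per cluster over 11 stretch levels,
the missingness scenario at 2 × 50 individuals × 20,000 SNPs, SNP selection
at 2 × 100 individuals × 5,000 SNPs, and topology recovery over 100
simulation seeds at 4 × 30 individuals × 1,000 SNPs. These sizes were
chosen so the full suite completes in well under a minute per scenario
while keeping every stochastic margin wide (the measured quantities sit far
from their thresholds at these sizes).

## Known limitations

- The MC-kernel is built from a single MST: datasets whose structure is
  destroyed by one spurious bridge edge (heavy outliers between clusters)
  will embed poorly; the generators log no warning for this.
- Exact rank-sum enumeration is limited to small groups; beyond that, the
  normal approximation's accuracy in the extreme tails is the usual
  large-sample caveat.
- The Balding–Nichols generator draws SNPs independently — no linkage
  disequilibrium — so threshold behaviour of PCA on real, correlated
  panels will differ quantitatively.
- `read_vcf_genotypes()` handles biallelic GT records only; multiallelic
  records are skipped, not split.
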