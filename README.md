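# ncmce

Nonlinear population-structure detection for genotype matrices with
**non-centred Minimum Curvilinear Embedding (ncMCE)**, plus the companion
tooling needed to use it in practice: a PCA baseline, a one-dimensional
cluster-separability score, missing-genotype imputation, rank-sum SNP
selection, UPGMA population dendrograms, and synthetic data generators for
end-to-end validation.

## The problem

Principal Component Analysis is the standard first look at a genotype matrix
(individuals × SNPs, coded 0 = homozygous wild-type, 1 = heterozygous,
2 = homozygous variant, 3 = missing): project the individuals onto the top
principal components and look for groups. PCA is linear, so it can miss
population structure that lies on a curved manifold of the
high-dimensional genotype space — subtly diverged ethnic groups, or
structure distorted by artefacts such as missing calls. ncMCE is a
parameter-free, nonlinear companion to PCA for exactly these cases.

## The method

For a data matrix **G** (n individuals × m SNPs):

1. **A** — pairwise distances between individuals under a chosen norm
   (Euclidean by default, or 1 − Pearson correlation), viewed as a complete
   weighted graph;
2. **T** — the minimum spanning tree of that graph;
3. **D** — the *MC-kernel*: all pairwise distances re-measured along the
   unique paths of **T**. Tree distances approximate curvilinear (geodesic)
   distances along the data manifold, and **D** is an additive tree metric;
4. the economy-size SVD **D** = U S Vᵀ; the coordinate of individual *j* on
   embedding dimension *k* is √(S_k) · V[j, k].

MCE double-centres **D** with J = I − (1/n)·11ᵀ before the SVD; ncMCE skips
the centring. For the non-centred kernel, dimension 1 mostly carries overall
magnitude and group discrimination typically appears on **dimension 2**.

Separability along one embedding dimension is quantified by the
**C-score**: for each pair of labelled groups (P_i, P_j), with
f_ij = [#{x ∈ P_i, y ∈ P_j : p(x) > p(y)} + ½·ties] / (|P_i||P_j|), the
pair score is 2·|f_ij − ½| and the C-score is the mean over group pairs.
It is 1 when groups occupy disjoint intervals (perfectly blocked ordering)
and 0 for an exactly balanced interleave.

## Worked example

Two interleaved, nonlinearly curved 3-D clusters (the generator's default
geometry), embedded with ncMCE and with PCA:

```r
library(ncmce)

cc  <- make_curved_clusters(n_per_cluster = 100, stretch = 0, seed = 42)
emb <- embed_pipeline(cc$points, method = "ncMCE", d = 2)
best_cscore(emb, cc$labels, dims = 1:2)
#> C-score per dimension:
#>   Dim1   Dim2
#> 0.1482 1.0000
#> best: 1.0000 (Dim2)

best_cscore(pca_embed(cc$points, 2), cc$labels, dims = 1:2)
#> C-score per dimension:
#>   Dim1   Dim2
#> 0.7258 0.6236
#> best: 0.7258 (Dim1)
```

ncMCE separates the two clusters perfectly on its second dimension
(C-score 1.0) while no PCA projection does better than 0.73: the clusters
are nested curved sheets, and only the tree-geodesic kernel unrolls them.

The same pipeline applies to genotype matrices. Here two populations are
simulated under the Balding–Nichols drift model (F_ST ≈ 0.2) and recovered
from the genotypes alone:

```r
g <- simulate_genotypes(0.2, n_ind_per_pop = 25, n_snps = 2000, seed = 42)
best_cscore(embed_pipeline(g, "ncMCE", d = 2), g$labels, dims = 1:2)
#> C-score per dimension:
#>   Dim1   Dim2
#> 0.0656 1.0000
#> best: 1.0000 (Dim2)
```

A command-line front end (`exec/ncmce`) exposes the same operations as
subcommands (`embed`, `cscore`, `impute`, `test-snps`, `tree`, `simulate`,
`heatmap`); every run writes a JSON provenance record alongside its output.

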