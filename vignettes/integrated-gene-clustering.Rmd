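---
title: "Integrated gene clustering: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated gene clustering: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexgo)
```

## The model

`coexgo` clusters genes with a distance that combines two sources of
information: a genes × samples expression matrix `G` and a binary genes ×
functions annotation matrix `T` (typically Gene Ontology Biological
Process terms, optionally propagated to ancestors). The premise is that
coexpression alone is an unreliable indicator of biological connection —
two genes can be correlated because distinct biological programmes respond
in parallel to the same condition — whereas coexpression *between genes
already known to share functions* is much more likely to reflect a real
connection.

The construction proceeds in two steps.

**Decomposition into coexpressed biological functions.** A function is a
gene set `K^j` (the genes annotated to it). If those genes are not all
coexpressed, the function is split into the coexpressed sub-groups found
by hierarchical clustering of `K^j` on the correlation distance
`d(k,k') = 1 − cor(k,k')`. Each sub-group becomes one column of the
expanded matrix `T_coexp`. The split conserves all the margins of `T`:
for each function the sub-column margins add up to the function's margin,
and row margins and the grand total are untouched (these identities are
asserted at every build).

**Chi-square distance.** Genes are then compared as row profiles of
`T_coexp` under the correspondence-analysis chi-square metric, with column
weights `T_.. / card(K_l^j)`. Equivalently, the squared distances are
exactly the squared Euclidean distances between CA row coordinates of
`T_coexp` (checked against an independent SVD-based implementation in the
test suite). Two genes that share a function but are not coexpressed sit
in different sub-columns and are *pushed apart* by the weight of that
function — this is what makes the integration active rather than
decorative.

A standard algorithm — Ward hierarchical ascending classification, or
K-means in the CA coordinate space — produces the final partition at a
user-chosen number of clusters. There is deliberately no automatic
selection of the cluster count: the number of modules is an analysis
choice, not an estimate.

## Cluster evaluation

Each cluster is scored by two indicators, each with a permutation
p-value obtained by drawing size-matched gene sets without replacement
from the whole gene universe and counting the proportion of null values
strictly above the observed one:

* the **coexpression indicator (CI)**: the mean of all pairwise Pearson
  correlations in the cluster. Its maximum is 1; its minimum depends on
  the cluster size: with two internally coherent, mutually anti-correlated
  sub-groups the indicator reaches `−1/(n−1)` for even `n` and `−1/n` for
  odd `n`. Both extremes are verified exactly in the tests.
* the **biological homogeneity indicator (BHI)**: one minus the
  chi-square discrepancy of the cluster's own gene × function subtable,
  normalized by the subtable total times `n − 1` (a form of Cramér's V).
  It is 1 when all profiles in the cluster are identical, 0 when no
  function links two cluster genes and each function is private to a
  single gene, and always within `[0, 1]` because the chi-square statistic
  of a contingency table is bounded by its total times the smaller
  dimension minus one. The margins in this statistic are those of the
  cluster's subtable: with full-matrix margins the indicator degenerates
  into a sum of per-gene terms and no longer measures within-cluster
  similarity at all, and the analytic extremes above are not attainable.

Because both indicators drift mechanically with cluster size, only the
permutation p-values are comparable across clusters. Singleton clusters
are not tested and are counted as bad candidates in partition summaries.
The p-value is the plain exceedance proportion (it can be exactly 0); a
`(b+1)/(B+1)` estimator is available via `correct = TRUE` for users who
need strictly positive estimates.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `alpha0` | 0.10 | threshold of the function-coexpression filtering step; `alpha0 >= 1` disables splitting entirely, making the distance the plain chi-square distance on `T` |
| `B` | 500 (decomposition), 1000 (evaluation) | permutations per test |
| `alpha` | 0.05 | significance threshold for CI/BHI p-values |
| `L_max` | 10 | cap on sub-clusters per function; unbounded splitting would allow degenerate all-singleton decompositions |
| `min_genes` | 2 | smallest function kept; a single-gene function carries no between-gene information |
| `n_clusters` | — | required user input |
| `beta` | 6 | soft-threshold power of the network comparator |

## Numerical and design choices

* **Tree cutting.** The partition used to split a function maximizes the
  ratio of successive inertia losses `D(L)/D(L+1)`,
  `D(L) = W(L−1) − W(L)` — the elbow rule of hierarchical ascending
  classification. Ties break toward fewer clusters; two items force a
  split. Within-cluster inertia is computed from the squared correlation
  distances, which is Ward's criterion, hence Ward linkage throughout.
* **Squared versus unsquared distances.** The chi-square distance is
  stored squared (`is_squared` flag); Ward clustering and the MDS/CA
  embedding take the square root, so the metric consumers always see a
  true metric and Ward never double-squares.
* **Sub-cluster ordering.** Within a function, sub-clusters are ordered
  by decreasing size, ties by smallest gene index, so `T_coexp` is fully
  reproducible.
* **Null caching.** Within one decomposition or one partition evaluation,
  permutation null distributions are cached per cluster size — the null
  law depends only on the data matrix and the size. All draws flow from a
  single top-level seed fanned out to named sub-streams, so every run is
  bit-reproducible.
* **Degenerate inputs.** Constant-expression genes, missing values and
  conflicting duplicate rows are rejected at load with named errors.
  Genes left without annotations are retained in the matrix but flagged,
  and excluded before the chi-square distance (their profiles are
  undefined); the pipeline reconciles expression and annotation universes
  by intersection and reports the drop count.
* **Ancestor propagation** uses `is_a` edges by default; `part_of` is
  optional because annotation pipelines differ on whether it is a safe
  generalization. Evidence codes are kept unless explicitly excluded.

## What the simulator emulates — and what it does not

`simulate_dataset()` produces paired data with a known truth:

* expression is multivariate Gaussian with equicorrelated planted blocks
  (defaults `K = 300`, `I = 10`, 20 equal blocks, within-block correlation
  0.85, between-block 0) — the minimal structure with genuine clusters of
  coexpressed genes;
* structured annotations are the non-root internal nodes of the gene
  classification tree built from expression correlations, so coexpressed
  genes mechanically share functional profile structure, mimicking the
  nested GO hierarchy (any two columns are nested or disjoint);
* random annotations are `r` row-permuted copies of the structured
  columns, conserving each function's margin (its degree of specificity)
  exactly while destroying its link to expression.

The root node is excluded: an all-ones column carries no information and
its chi-square weight would be degenerate. Leaves are not functions (a
singleton function cannot contribute between-gene similarity).

The generator does **not** emulate microarray noise models, missing data,
unequal block sizes, overlapping modules, or a DAG-shaped (non-tree)
annotation hierarchy. Passing benchmarks on these data therefore shows
that the pipeline behaves as designed under its own stated conditions,
not that it will rank methods identically on any real data set.

Two couplings of this design are worth knowing when reading benchmark
output. First, the heatmap baseline (Ward on the correlation distance) is
built from the *same tree* that generates the structured annotations, so
its clusters are tree nodes by construction and their homogeneity
p-values are essentially always significant — the baseline is flattered
by the generator. Second, a full binary classification tree contains many
two-gene nodes; when their permuted copies fail the coexpression filter
they split into single-gene columns whose chi-square weight is the full
association total. These heavy private columns are what drives the
integration method's singleton clusters, and singleton clusters count
against all three summary percentages.

## Problem sizes used by the tests

Unit and property tests run on toy matrices (6–150 genes, 3–20 samples)
with fixed seeds. The benchmark acceptance checks use 20 replicate
datasets per randomness intensity at `K = 300`, `I = 10`, 20-cluster
partitions and 500 permutations per test; the indicator-range property
suite draws 1,000 randomized clusters; the null-uniformity check uses 200
random clusters with fresh 500-draw nulls each. These sizes were chosen so
the whole suite documents the method's behavior at the benchmark's own
scale while remaining comfortably reproducible on a laptop.

## Known limitations

* The method yields a non-negligible proportion of single-gene clusters
  (rare, heavily weighted coexpressed functions isolate their genes);
  these are automatically bad candidates, which mechanically lowers the
  good-candidate percentage.
* The chi-square metric is sensitive to rare columns in general — a known
  property of correspondence analysis; `filter_functions()` with a higher
  `min_genes` is the pragmatic mitigation on real annotation sets.
* BHI is a purely structural surrogate for biological homogeneity;
  enrichment analysis and expert reading remain the final arbiter.
* No multiple-testing correction is applied across clusters: p-values are
  reported raw, per cluster, as screening aids.
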