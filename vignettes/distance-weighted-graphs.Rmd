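---
title: "Distance-weighted spatial graphs: model, design choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-weighted spatial graphs: model, design choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwgcn)
```

## The model

A spatial transcriptomics section is a set of N spots with 2D coordinates
$p_i$ and per-spot expression profiles. GCN-based domain identification
propagates features through a normalized adjacency matrix
$\tilde A$, so the geometry encoded in $\tilde A$ determines what each
layer averages. This package builds two competing operators from the same
coordinates:

**Distance-weighted (row-stochastic).** Raw Euclidean distances
$d^0_{ij} = \lVert p_i - p_j\rVert_2$ are rescaled by the mean
nearest-neighbour distance
$\bar d_{\min} = \tfrac1N \sum_i \min_{j\ne i} d^0_{ij}$ into relative
distances $d_{ij} = 1 + d^0_{ij} / \bar d_{\min}$. Each spot keeps its
$k$ nearest neighbours (directed, no symmetrization) plus a self-loop;
edges get inverse-distance weights $W_{ij} = d_{ij}^{-p}$; each row is
divided by its own sum. Because $d_{ii} = 1$ exactly and $d_{ij} > 1$
otherwise, the self-loop is the strict row maximum whenever $p > 0$, and
the relative ordering of neighbour weights survives normalization.

**Baseline (symmetric degree-normalized).** The binary KNN graph is
symmetrized by the union rule, self-loops are added, and
$\tilde A = D^{-1/2} A D^{-1/2}$ with $D_{ii} = \sum_j A_{ij}$. On a
regular lattice all interior entries collapse to $1/(k+1)$: geometry is
erased before propagation.

Assumptions worth stating: coordinates are 2D and Euclidean (no geodesic
or tissue-curvature distances); edges encode spatial proximity only,
never expression similarity; and the section has no exactly duplicated
coordinates (a duplicated spot makes $\bar d_{\min}$ degenerate — see
*Degenerate inputs*).

## Parameters that matter

* **k (neighbourhood size, default 12).** On a hexagonal array k = 12
  covers exactly the first two neighbour rings. Larger k widens the
  averaging radius and increases over-smoothing pressure; k above N−1 is
  truncated with a warning so tiny fixtures remain usable.
* **p (decay exponent, dimensionless, default 2).** p = 0 reproduces
  uniform within-neighbourhood weights (though the graph stays
  asymmetric); moderate p (0.5–1) begins to separate near from far;
  p = 2 is a balanced regime — on the ideal hexagonal lattice the
  interior profile is self 0.3027, first ring 0.0757, second ring
  0.0406; by p = 8 the self-weight exceeds 0.97 and propagation barely
  moves features. The normalized self-weight is monotone non-decreasing
  in p and tends to 1, because every off-diagonal $d_{ij}^{-p}$ decays
  while the self term is pinned at 1. These interior-node values are
  specific to the ideal lattice geometry; irregular sections and boundary
  spots give different (but identically ordered) profiles, so the
  ordering self > near > far, not any particular decimal, is the
  characteristic signature.
* **Relative scaling.** Multiplying all coordinates by any c > 0 leaves
  the weighted adjacency unchanged to 1e-12, which is what makes one
  (k, p) setting transferable across platforms with different spot
  pitches.

## The reference pipeline

The adjacency scheme is designed to be dropped into existing GCN
architectures; to test it in isolation this package ships a deliberately
minimal pipeline instead of wrapping any external framework. The default
`parameter_free` mode applies the adjacency L times to preprocessed
features (library-size normalization to the median depth, log1p, top
3000 variable genes, 50 principal components), projects to
`hidden_dims = 20` by truncated SVD, and clusters with k-means
(10 restarts, fixed seed). It has no trained weights, so any accuracy
difference between arms is attributable to the adjacency alone. L = 2
follows the shallow-architecture convention of spatial GCNs; linear
activation keeps the mode a pure smoothing operator. An `autoencoder`
mode (two-layer GCN encoder, linear decoder, full-batch Adam on squared
reconstruction error) demonstrates the propagation rule with learnable
weights; it reports its final loss and warns rather than silently
swallowing a non-improving fit. The number of clusters is always taken
from ground truth (simulations) or supplied by the user — no model
selection. Run-to-run stochasticity enters only through the clustering
(and, in autoencoder mode, training) seed; run r of R uses seed + r − 1,
so the two arms are aligned run-for-run for paired analysis.

## The simulator

Simulated sections place 3/5/8/10 spatially contiguous domains
(Voronoi partitions by default) on a 30 × 30 hexagonal lattice and draw
counts for M = 2000 genes from a negative binomial with variance
$\mu + \mu^2/\theta$ (mean/dispersion parameterization, stated because
conventions vary). Each domain owns a disjoint 5% block of marker genes
elevated 3-fold; dispersion is 2; per-spot library sizes are log-normal
with sd 0.2; gene baselines are log-normal around mean 1. These defaults
put the reference pipeline in a regime where clustering is good but not
saturated, so adjacency quality is measurable. Each scenario generates
eight independent replicates (independent domain draws and counts) from
seeds derived by a splittable counter, so replicate streams are
decorrelated and a base seed regenerates the whole scenario
bit-identically.

What the simulator does **not** emulate: real morphology (domain
boundaries here are polygonal), spatially varying spot density, within-
domain expression gradients, gene–gene correlation beyond shared domain
means, segmentation errors, and platform artefacts. Passing benchmarks on
this generator therefore demonstrate the *direction* of the adjacency
effect under clean geometry — not the magnitude to expect on real tissue,
where noise and irregularity shrink (but in our experience do not
reverse) the gap.

## Benchmarking statistics

For each sample s and run r the improvement is
$\Delta_{s,r} = \text{value}^{dw}_{s,r} - \text{value}^{ori}_{s,r}$ in
each of ARI, NMI, and Homogeneity. Sample-level tests apply the
two-sided Wilcoxon signed-rank test to a sample's run-wise deltas;
dataset-level tests apply it to the per-sample mean deltas (run-wise
differences are averaged within each sample first — pooling all runs
would overweight samples and treat correlated runs as independent).
Benjamini–Hochberg correction runs separately within the sample-level and
dataset-level families, since the two levels are reported side by side.
Cliff's delta is computed over all n × m cross pairs of the two arms'
values, matching its definition as
$P(X_{dw} > X_{ori}) - P(X_{dw} < X_{ori})$, with the conventional
magnitude labels at 0.147/0.33/0.474. Zero deltas are discarded before
ranking; an all-zero comparison reports p = 1 with a degenerate flag
rather than an error. The exact signed-rank null is enumerated for
n ≤ 25 without ties, otherwise the normal approximation with tie and
continuity corrections is used. NMI is normalized by the arithmetic mean
of the marginal entropies (one convention fixed package-wide; all
internal comparisons use it on both arms, so the choice cannot tilt a
comparison). Homogeneity is defined as 1 when the truth has a single
class — degenerate but total.

## Numerical choices and degenerate inputs

* Distances and weights are computed in dense 64-bit arithmetic; the
  dense path is exact at every N in scope, and the brute-force oracle
  tests assert entrywise agreement within 1e-12.
* KNN ties are broken by ascending spot index — deterministic graphs
  across platforms.
* Duplicate coordinates are a hard error by default (the
  nearest-neighbour scale is undefined); an opt-in jitter of
  1e-6 × $\bar d_{\min}$ resolves them explicitly rather than silently.
* Row sums are asserted to be within 1e-9 of 1 after normalization.
* Truncated-SVD projections fix the sign of each component (largest-
  magnitude coordinate positive) so embeddings are bit-reproducible.
* $\bar d_{\min}$ is computed globally over all spots, as its definition
  reads, not per KNN candidate set.
* The dataset-level Wilcoxon uses per-sample mean deltas (the
  alternative — pooling run-wise deltas — inflates n with correlated
  observations).

## Validation problem sizes

The test suite validates the graph algebra against dense brute-force
re-implementations on random point sets up to N = 200 across
k ∈ {4, 6, 12} and p ∈ {0, 0.5, 1, 2, 4}, the statistics against full
2^n sign enumeration and exhaustive pair counting, and the end-to-end
effect on 8-replicate scenarios at 900 spots × 2000 genes with 5 runs
per arm — sizes chosen so the full suite exercises every claim on a
single CPU in about a minute while keeping the simulations in the
mid-accuracy regime described above.

## Limitations

Only 2D coordinates and Euclidean proximity are supported; the reference
pipeline is a measurement instrument, not a state-of-the-art clustering
method; simulated magnitudes do not transfer to real tissue; and optimal
(k, p) depend on spot density and tissue granularity — the defaults
(12, 2) are a stable, representative setting, not a per-dataset optimum.
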