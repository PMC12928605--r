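# dwgcn

Distance-weighted spatial graphs for GCN-based spatial domain
identification in spatial transcriptomics.

## The problem

Sequencing-based spatial transcriptomics measures an expression profile at
each of N capture spots with known 2D coordinates. Identifying *spatial
domains* — spatially coherent tissue regions with a shared expression
signature — is usually done by clustering graph-convolutional embeddings,
where a GCN layer aggregates each spot's neighbourhood through a
normalized adjacency matrix. The standard construction (binary KNN graph,
symmetrized, self-loops, symmetric degree normalization
`Ã = D^(-1/2) A D^(-1/2)`) produces nearly uniform weights — on a regular
lattice with k = 12 every neighbour and the self-loop get 1/13 ≈ 0.077 —
so spatial distance has almost no influence on message passing, repeated
propagation over-smooths, and fine domain boundaries blur.

This package implements the distance-weighted alternative and the
machinery to measure its effect:

1. **Relative distances** — `d_rel(i,j) = 1 + d0(i,j) / d̄_min`, where
   `d̄_min` is the mean nearest-neighbour distance over the section.
   This makes weights invariant to the platform's spot pitch and pins the
   self-distance at exactly 1.
2. **Asymmetric KNN graph** — each spot keeps its k nearest neighbours
   (no symmetrization; directional structure is retained) plus a
   self-loop.
3. **Inverse-distance weights** — `W(i,j) = d_rel(i,j)^(-p)`; the decay
   exponent p ≥ 0 tunes locality, and the self-loop weight is always 1
   before normalization.
4. **Row normalization** — each row divided by its own sum, giving a
   row-stochastic propagation operator that preserves the within-row
   ordering of distance-derived weights and keeps the self-loop the
   strict row maximum for every p > 0.

Around that core the package provides a reference GCN
propagation/clustering pipeline (so the two adjacency kinds can be
compared with everything else held fixed), a negative-binomial simulator
of spatial domains on hexagonal/square lattices, and the paired
benchmarking statistics: run-wise deltas, Wilcoxon signed-rank tests,
Benjamini–Hochberg FDR, and Cliff's delta, at sample and dataset level.

## Worked example

```r
library(dwgcn)

st <- make_lattice(lattice_spec("hexagonal", 21, 21))
a  <- build_dw_adjacency(st, k = 12, p = 2)
a
#> adjacency [dw_row_normalized]: 441 x 441, k = 12, p = 2

ctr <- which.min(colSums((t(st$coords) - colMeans(st$coords))^2))
w <- a$matrix[ctr, ]
round(sort(unique(round(w[w > 0], 6)), decreasing = TRUE), 4)
#> [1] 0.3027 0.0757 0.0406
```

At an interior node of an ideal hexagonal lattice with k = 12 and p = 2,
the self-loop carries weight 0.3027, the six nearest neighbours (relative
distance 2) get 0.0757 each, and the six second-ring neighbours (relative
distance 1 + √3) get 0.0406 each: self > near > far, instead of the
baseline's uniform 0.077. At p = 0 the rows are uniform at 1/13; at p = 8
the self-loop exceeds 0.97.

A small paired benchmark on simulated 5-domain tissue:

```r
sets  <- make_scenario("cluster_5", n_replicates = 2, base_seed = 11)
bench <- benchmark_datasets(sets, pipeline_config(n_runs = 3, seed = 1))
bench$report$dataset_level[, c("metric", "mean_delta", "fdr", "cliffs_delta")]
#>        metric mean_delta fdr cliffs_delta
#> 1         ARI     0.0431 0.5            1
#> 2 Homogeneity     0.0408 0.5            1
#> 3         NMI     0.0409 0.5            1
```

`mean_delta` is the mean run-wise improvement (distance-weighted minus
baseline arm) in each metric; `cliffs_delta = 1` means every
distance-weighted run beat every baseline run. (With only 2 samples the
dataset-level Wilcoxon cannot reach significance; the full design uses 8
replicates.)

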