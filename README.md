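# samgraph

Self-assembling manifold reconstruction for single-cell expression data:
iterative **soft feature selection** coupled to **kNN-graph refinement**.

## The problem

Most scRNA-seq pipelines pick a hard list of "highly variable genes" before
dimensionality reduction. That works when cell types differ in hundreds of
strongly variable genes, but fails on datasets whose populations are
separated by subtle, low-variance programs — the informative genes never
make the HVG cut, and the embedding is built from noise. `samgraph` instead
lets the data decide *iteratively*: a gene's usefulness is scored by how much
its expression varies **across neighborhoods of the current cell graph**
rather than across individual cells, and the graph is rebuilt from the
reweighted data until the two agree.

## The algorithm

Given a log-scale expression matrix `E` (n cells × m genes) and a random
directed kNN graph `N` (k out-edges per cell, self included), iterate:

1. **Neighborhood averaging** — `C = (1/k) N E`.
2. **Spatial dispersion** — per gene, the Fano factor of the averaged
   expression, `F_i = σ²(C_i) / μ(C_i)` (population variance). Genes that
   vary along the graph topology score high; genes that vary only
   cell-to-cell are averaged away.
3. **Saturated weights** — `W_i = min(F_i, z) / z` with `z` the mean of the
   top-N dispersions (N = 50), giving weights in [0, 1].
4. **Rescale and embed** — multiply the standardized (or L2-normalized)
   matrix by `diag(W)`, mean-center, SVD `Ê_μ = U S Vᵀ`; keep **all**
   components `P = U S` and scale them by their eigenvalues
   `Λ = S²/(n−1)`: `P̂ = P Λ`.
5. **Graph update** — pairwise Pearson-correlation (or Euclidean) distances
   between rows of `P̂`; each cell's neighbors become itself plus its k−1
   nearest cells.

Stop when the RMSE between consecutive weight vectors drops below 5×10⁻³.

Around the core loop the package provides the matching benchmarking
machinery: graph-quality metrics (network-average clustering coefficient,
Newman modularity, the Euclidean norm of the top spatial dispersions),
Louvain and density-based clustering with kNN outlier rescue, the adjusted
Rand index with a per-cluster decomposition, a network-sensitivity statistic
(distance-matrix disagreement across random gene subsamples), a
matrix-corruption robustness benchmark with trapezoidal AUC,
gene-set-associated PC removal (cell-cycle style confound regression), and
seeded synthetic-data generators (Poisson-gamma null, planted clusters,
HVG-trap noise genes, latent confound signatures).

## Worked example

```r
library(samgraph)

ds  <- canonical_fixture(0)        # 300 cells x 2000 genes, 3 planted clusters,
                                   # 10 four-fold marker genes each; preprocessed
fit <- run_sam(ds$E, seed = 1, max_iter = 20)
fit
#> SAM fit: 300 cells, 1962 genes
#>   iterations: 5 (converged)
#>   final weight RMSE: 0.001954
#>   saturation level z: 0.2394

fit$trace
#>   iteration weight_rmse adjacency_error
#> 1         1          NA          0.8862
#> 2         2 0.347760361          0.7528
#> 3         3 0.095370836          0.1943
#> 4         4 0.014861911          0.0137
#> 5         5 0.001953643          0.0008

lab <- density_cluster_with_rescue(fit$pca)
ari(lab, ds$labels)
#> [1] 1

wt <- weight_table(fit)
sort(match(unlist(ds$markers), wt$gene))
#>  [1]  1  2  3 ... 30          # all 30 planted markers rank first
```

The trace shows the two convergence diagnostics per iteration: the RMSE
between adjacent weight vectors and the fraction of kNN edges that changed.
Both collapse as the graph and the weights lock onto the planted structure;
the 30 marker genes end up with the 30 largest weights, and density
clustering of the eigenvalue-weighted embedding recovers the planted labels
exactly (ARI = 1).

A thin CLI over the same functions lives at `inst/cli/sam.R`
(`simulate`, `run`, `cluster`, `metrics`, `sensitivity`, `corrupt-bench`,
`remove-confound`), reading/writing Matrix Market, TSV, `.rnk` and JSON.

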