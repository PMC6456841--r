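# clustgrain

Cluster granularity assessment for single-cell RNA-seq via inter-cluster
differential expression.

## The problem

Every scRNA-seq clustering algorithm has a resolution parameter, and the
number of clusters it reports is largely a function of that parameter, not
of the biology. Too coarse and rare cell types vanish into their
neighbours; too fine and a single population is split into "clusters" that
no experiment could tell apart. `clustgrain` takes a biology-first view of
this choice: a cluster boundary is only meaningful if genes are
differentially expressed across it strongly enough that the two sides
could be distinguished *in situ* (e.g. by RNA FISH for a marker gene).

## The method

For a log-normalized expression matrix (genes × cells, with known log
base and normalization pseudocount) and one or more cluster solutions,
the package precomputes, per solution:

- **Cluster-wise gene statistics** on the de-logged normalized-count
  scale: detection rate `DR` (fraction of cells with non-zero
  expression), mean detected expression `MDGE` (mean over expressing
  cells only) and mean expression `MGE = DR × MDGE`.
- **Differential expression**: Wilcoxon rank-sum tests for each cluster
  versus the pooled rest and for all cluster pairs. A gene is tested in a
  comparison only if `DR ≥ 10%` on at least one side; p-values are
  Benjamini–Hochberg adjusted within each comparison's tested set.
- **Effect sizes**: the detection-rate difference `dDR = DR_A − DR_B`,
  and the log2 gene expression ratio
  `logGER = log2((m_A + pc) / (m_B + pc))` over normalized-count means.
  The pseudocount `pc` defaults to `1/N` for `N` cells — the smallest
  observable step in count data. A pseudocount of 1 systematically
  compresses ratios between low-abundance means, while a vanishing
  pseudocount throws comparisons with zero past magnitude 300; `1/N`
  avoids both (see `pseudocount_comparison()`).
- **Granularity metrics**: *marker genes* (`de_marker()`; positively DE
  against every other cluster at FDR 5%) and *neighbour DE*
  (`de_neighb()`; positively DE against the nearest neighbouring
  cluster, i.e. the cluster with the fewest DE genes in between).
- **Silhouette widths** on a user-supplied reduced-dimension embedding
  (Euclidean, no axis reweighting).

`sweep_resolutions()` assesses solutions in order of increasing cluster
count. A solution *passes the neighbour check* when every cluster has at
least one positively DE gene against its nearest neighbour; with
`stop_on_loss = TRUE` the sweep halts at the first failure — the
operational definition of over-clustering.

## Worked example

```r
library(clustgrain)
sim    <- simulate_dataset(simulation_spec(seed = 1))   # 5 true clusters
series <- build_resolution_series(sim$labels, sim$matrix,
                                  ks = c(3, 5, 6), seed = 1)
sw <- sweep_resolutions(sim$matrix, series, sim$embedding,
                        stop_on_loss = TRUE)
sw
#> scv_sweep: 3 solution(s) assessed
#>  solution_id n_clusters min_neighb_de median_neighb_de total_markers
#>           k3          3             8               10            28
#>           k5          5            10               10            48
#>           k6          6             0                9            36
#>  mean_silhouette passed
#>        0.2679761   TRUE
#>        0.8440154   TRUE
#>        0.6732032  FALSE
```

The 5-cluster solution (the truth: each cluster has 10 exclusive
simulated DE genes) passes with ~10 neighbour-DE genes per cluster and
the best mean silhouette. The 6-cluster solution — the truth with one
cluster split at random — has a cluster with **zero** genes
distinguishing it from its neighbour, fails the check, and stops the
sweep. Per-cluster detail:

```r
summary(sw$scvs[["k5"]])
#> Assessment of cluster solution 'k5'
#>  cluster n_cells neighb_de markers mean_silhouette
#>       c1      40        10       9       0.8525222
#>       c2      40        10      10       0.8471473
#>       c3      40        10      10       0.8621468
#>       c4      40        10      10       0.8396155
#>       c5      40        11       9       0.8186452
#> passed neighbour check: TRUE
```

`de_marker(sw$scvs[["k5"]])` then returns the marker genes per cluster
(here recovering 9–10 of each cluster's 10 simulated DE genes), and
`save_results_archive()` persists everything as an open TSV/JSON archive.
The same workflow is scriptable from a shell via the `clustgrain` CLI
(`inst/cli/clustgrain`): `simulate`, `prep`, `assess`, `markers`,
`annotate`, `compare`, `plot`.

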