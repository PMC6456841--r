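---
title: "Assessing cluster granularity by inter-cluster differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing cluster granularity by inter-cluster differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustgrain)
```

## Motivation and model

Clustering scRNA-seq data always yields *some* partition; the scientific
question is whether the partition's boundaries correspond to
transcriptionally distinct cell populations. `clustgrain` operationalizes
this with differential expression (DE): a cluster earns its existence only
if genes are statistically separably expressed between it and the cluster
it is hardest to distinguish from. This vignette explains the statistical
choices, the tunable parameters, what the synthetic validation data do and
do not show, and the numerical conventions.

## Scales, logs and pseudocounts

Input is a genes × cells matrix of log-normalized expression, with the
log base $b$ and normalization pseudocount $c$ declared by the user
(defaults $b = 2$, $c = 1$, the most common convention; pipelines using
the natural log must say so). Means of log values underestimate means of
counts badly for sparse data, so every statistic is computed after
de-logging, $x = b^v - c$:

* detection rate $DR$ — fraction of a cluster's cells with $x > 0$;
* mean detected expression $MDGE$ — mean of $x$ over expressing cells
  (defined as 0 when no cell expresses the gene, keeping tables dense);
* mean expression $MGE$ — mean of $x$ over all the cluster's cells.

These satisfy $MGE = DR \times MDGE$ identically; the test suite asserts
the identity at $10^{-12}$ relative tolerance.

The effect size for a comparison of groups $A$, $B$ is the log2 gene
expression ratio over normalized-count means,
$\mathrm{logGER} = \log_2\!\frac{\bar{x}_A + p}{\bar{x}_B + p}$.
The choice of $p$ matters more than is commonly appreciated:

* $p = 1$ — the bulk-transcriptomics habit — compresses every ratio,
  and worst exactly where scRNA-seq lives, at means near zero
  ($|\mathrm{logGER}| \le |\log_2(\bar{x}_A/\bar{x}_B)|$ always, with
  the deficit largest for small means);
* $p = 10^{-99}$ keeps finite ratios honest but sends any comparison
  with an undetected gene beyond magnitude 300, detached from the rest
  of the scale;
* $p = 1/N$, the reciprocal of the number of cells — the smallest
  step a count matrix can represent after depth normalization — keeps
  finite ratios within 0.1 of truth for means ≥ 1 while bounding
  zero-comparisons near the data's range.

`pseudocount_comparison()` reproduces all three behaviours on a
deterministic 15-point grid of means spanning 0–50 (one exact zero, the
rest evenly spaced; the source material does not state its sampling
scheme, so an even grid is used); the acceptance script reports the
minimum zero-comparison magnitude under $p = 10^{-99}$. The package
default for DE results is $p = 1/N$ with $N$ the total cells in the
dataset (not per cluster), stored in the fitted object.

## Testing machinery

Significance uses the two-sided Wilcoxon rank-sum test: non-parametric,
robust to the unbalanced comparisons of cluster-vs-rest, invariant to
the log transform, and trivially parallel. The implementation is exact
(via the null Mann–Whitney distribution) for tie-free pooled samples of
at most 50, otherwise the tie-corrected normal approximation with
continuity correction; the suite checks it against exhaustive
enumeration for all pooled sizes ≤ 12 and against the conventional
base-R implementation in both regimes. Rank-based tests are biased
toward sparsely detected genes, so a gene enters a comparison only if
$DR \ge$ `dr_threshold` (default 10%) on at least one side. For
cluster-vs-rest the filter uses the pooled rest's detection rate — the
source material leaves this open; pooling is the interpretation used
here. Per comparison, p-values are Benjamini–Hochberg adjusted over
that comparison's tested genes only (not globally), matching the
per-table layout of the results; `logGER` (and `dDR` for pairwise
tables) is reported for *all* genes, tested or not.

"Positively DE toward cluster $c$" means FDR < `fdr_threshold`
(default 5%) *and* effect sign toward $c$; a zero effect is never
positive. Two granularity readouts derive from the pairwise tables:

* **markers** — genes positively DE toward $c$ in *every* pair
  $(c, \cdot)$; the strict criterion, guaranteeing a unique signature;
* **neighbour DE** — genes positively DE toward $c$ against its
  nearest neighbour, the cluster with the fewest significant genes
  (counted in both directions) in between. Ties in the neighbour
  argmin break by cluster-name order, and the relation is deliberately
  not symmetrized. Because markers quantify over a superset of pairs,
  $\mathrm{marker}(c) \subseteq \mathrm{neighb}(c)$ always.

A solution **passes the neighbour check** when every cluster's
neighbour-DE set is non-empty. `sweep_resolutions()` orders solutions
by cluster count (stable on ties) and, with `stop_on_loss`, stops after
the first failing solution — which is retained and flagged, so the
failure can be inspected rather than silently dropped. Single-cluster
solutions have no pairs; their flag is `NA` and they never trigger the
stop.

## Silhouette analysis

As a geometry-based complement, per-cell silhouette widths
$s_i = (b_i - a_i)/\max(a_i, b_i)$ are computed on a user-supplied
embedding ($a_i$: mean Euclidean distance to own-cluster cells; $b_i$:
smallest mean distance to another cluster). Conventions: singleton
clusters and degenerate $\max(a,b)=0$ cases get width 0. Coordinates
are used exactly as given — principal components are *not* reweighted
by variance explained, so users should pass the same space their
clustering used. The embedding is consumed, never computed: upstream
dimensionality reduction is out of scope.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `log_base`, `norm_pseudocount` | 2, 1 | — | must match the upstream normalization or de-logged means are wrong |
| `dr_threshold` | 0.10 | proportion | excludes genes whose ranks are mostly ties of zeros |
| `fdr_threshold` | 0.05 | proportion | significance for marker/neighbour sets and the stopping rule |
| `logger_pseudocount` | 1/N cells | normalized counts | keeps ratios finite without compression |
| `min_cells` (advisory) | 3 | cells | clusters smaller than this are flagged untestable |

## Synthetic validation data

`simulate_dataset()` draws counts from a negative binomial
($\mathrm{Var} = \mu + \phi\mu^2$, dispersion $\phi = 0.5$), gives each
cluster an exclusive block of DE genes whose mean is multiplied by the
effect size within that cluster, then library-size normalizes to the
median depth and log2-transforms with pseudocount 1. The NB zero mass
ties detection rate to expression magnitude, emulating the
dropout-expression correlation of droplet assays. Defaults define the
reference validation scenario used by the test suite: 5 clusters × 40
cells, 500 genes, 10 DE genes per cluster at 4× effect over a baseline
mean of 1.0 — chosen once as a sparse-but-informative regime (baseline
detection ≈ 0.55) representative of a well-powered droplet experiment,
and sized so the full 20-seed property suite runs in minutes on one
core. The generator also emits a synthetic 2-D embedding (Gaussian
blobs at per-cluster centres): ground truth for exercising the
silhouette code, not a computed reduction of the counts.

`build_resolution_series()` turns true labels into an under-/exact-/
over-clustered series. Under-clustering merges the closest cluster
centroids by balanced greedy pairing — the candidate pair with the
fewest already-merged members wins, falling back to distance — because
hierarchical merging of near-equidistant centroids can chain three
populations into one, producing a blended cluster that is legitimately
inseparable from its neighbour and so confounds the property being
tested (that *true* structure passes and *over-splits* fail).
Over-clustering bisects the largest cluster at random (seeded).

What passing these simulations shows: the pipeline detects designed
4-fold differences at the stated sample sizes, controls false
discoveries on null splits (observed discovery fraction ≤ 1% at FDR
5%), and the stopping rule halts precisely where structure runs out.
What it does not show: robustness to batch effects, doublets, ambient
RNA, continuous trajectories, or unequal cluster abundances — real
data violate the generator's exchangeable-cells assumption in all
these ways, and the neighbour check can only be as good as the
clustering and normalization upstream of it.

## Numerical conventions and edge cases

* De-logged values within $10^{-9}$ below zero are clamped to zero;
  anything lower is an error naming the offending gene and cell (it
  indicates wrong log base/pseudocount metadata).
* Cluster labels are always text (`"1"` ≠ `"01"`) and may not contain
  `-`, which separates the two names in pairwise table keys.
* Gene ranking within a cluster (used by the aggregate-rank annotation)
  sorts by MGE, then DR, then gene name; annotation aggregates by the
  arithmetic mean rank of the catalog genes present in the data,
  ignoring absent genes, and breaks type ties by name order. The rank
  statistic is configurable (MGE/MDGE/DR); MGE is the default because
  it blends magnitude and detection. This is a labelling convenience,
  not a claim of equivalence to dedicated classifiers.
* Volcano tables clamp FDR = 0 to half the smallest nonzero FDR before
  $-\log_{10}$.
* Archives are open directories of TSV/JSON (or a `.tar.gz` of one
  with pinned timestamps, making identical runs byte-identical); the
  manifest is validated against the files on reload, and numbers
  round-trip at full precision through the plain-text tables.

## Known limitations

The Wilcoxon test is conservative for scRNA-seq (its FDR control runs
below nominal), so neighbour-DE counts are a floor, not a ceiling;
model-based tests can be substituted by supplying their p/FDR/effect
columns in the same table schema. The neighbour check is a necessary
condition for a good resolution, not a sufficient one — it cannot
detect *under*-clustering, and the final choice of resolution remains
the analyst's.
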