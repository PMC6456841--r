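Package: clustgrain
Title: Cluster Granularity Assessment for Single-Cell RNA-Seq via
    Inter-Cluster Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how well a clustering of single-cell RNA-seq data
    reflects transcriptionally distinct cell populations, using
    differential gene expression between clusters as the yardstick. For
    each cluster solution it computes detection rates and mean expression
    statistics on the de-logged normalized-count scale, Wilcoxon rank-sum
    tests with Benjamini-Hochberg false discovery rate control for
    cluster-vs-rest and all pairwise comparisons, pseudocount-corrected
    log2 gene expression ratios, marker genes (positively differentially
    expressed against every other cluster) and nearest-neighbour
    differential expression, plus silhouette widths on a user-supplied
    embedding. A resolution sweep tests cluster solutions in order of
    increasing granularity and can stop once nearest-neighbour
    differential expression is lost, flagging over-clustering. Includes
    aggregate-rank cell-type annotation from marker catalogs, manual
    cell-set comparisons with volcano/MA statistics, a negative-binomial
    synthetic-data generator for validation, file-based archives of all
    results, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
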