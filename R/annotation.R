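#' Rank genes within a cluster
#'
#' Orders all genes of one cluster by decreasing mean gene expression
#' (`MGE` by default), breaking ties by decreasing detection rate and then
#' by gene name. Rank 1 is the most highly expressed gene. This ranking
#' underlies the aggregate-rank annotation in [annotate_clusters()].
#'
#' @param stats a [compute_cluster_gene_stats()] result.
#' @param cluster cluster name.
#' @param statistic which statistic to rank on: `"MGE"` (default),
#'   `"MDGE"` or `"DR"`.
#' @return Named integer vector of ranks (names are gene ids), covering
#'   every gene.
#' @export
rank_genes_in_cluster <- function(stats, cluster,
                                  statistic = c("MGE", "MDGE", "DR")) {
  stopifnot(inherits(stats, "cluster_gene_stats"))
  statistic <- match.arg(statistic)
  if (!cluster %in% names(stats))
    stop("unknown cluster: ", cluster)
  tab <- stats[[cluster]]
  ord <- order(-tab[[statistic]], -tab$DR, rownames(tab))
  r <- integer(nrow(tab))
  r[ord] <- seq_len(nrow(tab))
  stats::setNames(r, rownames(tab))
}

#' Read a cell-type marker catalog
#'
#' A marker catalog maps cell-type names to canonical marker genes.
#' Accepted formats: JSON (object of type -> array of gene ids) or a
#' two-column TSV (type, gene; a header line is detected and skipped).
#'
#' @param path file path (`.json` or tab-separated text).
#' @return Named list of character vectors, one per cell type.
#' @export
read_marker_catalog <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    cat0 <- jsonlite::read_json(path, simplifyVector = TRUE)
    cat0 <- lapply(cat0, as.character)
  } else {
    df <- utils::read.delim(path, header = FALSE,
                            colClasses = "character")
    if (ncol(df) != 2L)
      stop("marker catalog TSV must have exactly two columns (type, gene)")
    if (tolower(df[1, 1]) %in% c("type", "cell_type", "celltype"))
      df <- df[-1, , drop = FALSE]
    cat0 <- split(df[[2L]], df[[1L]])
  }
  validate_catalog(cat0)
  cat0
}

validate_catalog <- function(catalog) {
  if (length(catalog) == 0L) stop("marker catalog is empty")
  if (is.null(names(catalog)) || any(names(catalog) == "") ||
      anyDuplicated(names(catalog)))
    stop("marker catalog type names must be unique and non-empty")
  if (any(lengths(catalog) == 0L))
    stop("marker catalog contains a type with no genes")
  invisible(catalog)
}

#' Annotate clusters by aggregate marker-gene rank
#'
#' Assigns each cluster the cell type whose catalog genes have the best
#' (smallest) mean expression rank in that cluster. Catalog genes absent
#' from the data are ignored rather than penalized; a type with no genes
#' present is dropped from consideration. Ties go to the first type in
#' name order. This is a convenience labelling, not a substitute for
#' dedicated cell-type classification methods.
#'
#' @param stats a [compute_cluster_gene_stats()] result.
#' @param catalog named list of character vectors (type -> marker genes),
#'   e.g. from [read_marker_catalog()].
#' @param statistic rank statistic passed to [rank_genes_in_cluster()].
#' @return Data frame with one row per cluster: `cluster`, `cell_type`,
#'   `aggregate_rank` (mean rank of the winning type's present genes).
#' @export
annotate_clusters <- function(stats, catalog,
                              statistic = c("MGE", "MDGE", "DR")) {
  stopifnot(inherits(stats, "cluster_gene_stats"))
  statistic <- match.arg(statistic)
  validate_catalog(catalog)
  genes <- rownames(stats[[1L]])
  present <- lapply(catalog, intersect, genes)
  present <- present[lengths(present) > 0L]
  if (length(present) == 0L)
    stop("no catalog gene is present in the data for any cell type")
  types <- sort(names(present))           # name order = tie-break order
  rows <- lapply(names(stats), function(cl) {
    r <- rank_genes_in_cluster(stats, cl, statistic)
    agg <- vapply(types, function(ty) mean(r[present[[ty]]]), numeric(1))
    best <- types[which.min(agg)]         # which.min takes the first tie
    data.frame(cluster = cl, cell_type = best,
               aggregate_rank = agg[[best]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare two manually selected cell sets
#'
#' Builds a derived three-group labelling (`A`, `B`, and `rest` for the
#' remaining cells) and runs the full differential expression machinery on
#' it: all pairwise comparisons and, when a rest group exists, each group
#' versus the rest. The result behaves like an assessed pseudo-solution
#' and can be archived and explored like any cluster solution. When A and
#' B together cover all cells, the vs-rest comparison is skipped with a
#' warning.
#'
#' @param m a [norm_matrix()].
#' @param set_a,set_b character vectors of cell ids; disjoint, non-empty.
#' @param params a [de_params()].
#' @param comparison_id name for the comparison (default `"A-vs-B"`).
#' @return An object of class `c("cell_set_comparison", "scv")` whose
#'   pairwise slot contains the `"A-B"` (and, with a rest group,
#'   `"A-rest"`, `"B-rest"`) tables.
#' @export
compare_cell_sets <- function(m, set_a, set_b, params = de_params(),
                              comparison_id = "A-vs-B") {
  stopifnot(inherits(m, "norm_matrix"))
  set_a <- as.character(set_a); set_b <- as.character(set_b)
  if (length(set_a) == 0L || length(set_b) == 0L)
    stop("both cell sets must be non-empty")
  cells <- cell_ids(m)
  unknown <- setdiff(c(set_a, set_b), cells)
  if (length(unknown))
    stop("unknown cell id(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  if (length(intersect(set_a, set_b)))
    stop("cell sets overlap: ",
         paste(utils::head(intersect(set_a, set_b), 5L), collapse = ", "))
  lab <- rep("rest", length(cells))
  names(lab) <- cells
  lab[set_a] <- "A"; lab[set_b] <- "B"
  has_rest <- any(lab == "rest")
  if (!has_rest)
    warning("sets A and B cover all cells; vs-rest comparison skipped",
            call. = FALSE)
  s <- cluster_solution(lab, cells, solution_id = comparison_id)
  params$logger_pseudocount <- resolve_logger_pc(params, length(cells))
  stats <- compute_cluster_gene_stats(m, s)
  fit <- structure(list(
    solution_id = comparison_id,
    solution = s,
    stats = stats,
    de_vs_rest = if (has_rest) calc_de_vs_rest(m, s, stats, params),
    de_combn = calc_de_combn(m, s, stats, params),
    silhouette = NULL,
    params = params,
    n_cells = length(cells),
    set_a = set_a, set_b = set_b),
    class = c("cell_set_comparison", "scv"))
  fit
}

#' Volcano-plot table for one comparison
#'
#' Per tested gene, the effect size (`logGER`) and the significance score
#' `-log10(FDR)`. Untested genes are excluded. FDR values of exactly zero
#' are clamped to half the smallest nonzero FDR in the table (or to the
#' smallest positive double when all FDRs are zero) before the log.
#'
#' @param pair_table one element of a [calc_de_combn()] or
#'   [calc_de_vs_rest()] result.
#' @return Data frame: `gene`, `logGER`, `neg_log10_FDR`.
#' @export
volcano_table <- function(pair_table) {
  keep <- pair_table$tested
  fdr <- pair_table$FDR[keep]
  nz <- fdr[fdr > 0]
  clamp <- if (length(nz)) min(nz) / 2 else .Machine$double.xmin
  fdr[fdr == 0] <- clamp
  data.frame(gene = rownames(pair_table)[keep],
             logGER = pair_table$logGER[keep],
             neg_log10_FDR = -log10(fdr),
             stringsAsFactors = FALSE)
}

#' MA-style (mean-difference) table for two cell groups
#'
#' For each gene, the difference and average of one of the three gene
#' statistics (`MGE`, `MDGE` or `DR`) between two groups. Difference is
#' `A - B` (antisymmetric under a swap of the groups); average is the
#' midpoint (symmetric).
#'
#' @param stats_a,stats_b per-gene statistics data frames for the two
#'   groups (elements of a [compute_cluster_gene_stats()] result, same
#'   gene universe).
#' @param metric `"MGE"`, `"MDGE"` or `"DR"`.
#' @return Data frame: `gene`, `difference`, `average`.
#' @export
ma_table <- function(stats_a, stats_b, metric = c("MGE", "MDGE", "DR")) {
  metric <- match.arg(metric)
  if (!identical(rownames(stats_a), rownames(stats_b)))
    stop("the two statistics tables must cover the same genes")
  a <- stats_a[[metric]]; b <- stats_b[[metric]]
  data.frame(gene = rownames(stats_a),
             difference = a - b,
             average = (a + b) / 2,
             stringsAsFactors = FALSE)
}
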