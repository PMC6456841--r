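#' Differential-expression testing parameters
#'
#' Bundles the three thresholds that govern differential expression testing
#' between clusters.
#'
#' @param dr_threshold minimum detection rate (in at least one side of a
#'   comparison) for a gene to be tested; default 0.10.
#' @param fdr_threshold Benjamini-Hochberg FDR below which a comparison is
#'   called significant; default 0.05.
#' @param logger_pseudocount pseudocount added to both means in the log2
#'   gene expression ratio. `NULL` (default) means "decide per dataset":
#'   the reciprocal of the total number of cells, the smallest possible
#'   step in count-based data. A fixed value can be supplied instead.
#' @return An object of class `"de_params"`.
#' @export
de_params <- function(dr_threshold = 0.10, fdr_threshold = 0.05,
                      logger_pseudocount = NULL) {
  if (!is.numeric(dr_threshold) || length(dr_threshold) != 1L ||
      dr_threshold < 0 || dr_threshold > 1)
    stop("'dr_threshold' must be a proportion in [0, 1]")
  if (!is.numeric(fdr_threshold) || length(fdr_threshold) != 1L ||
      fdr_threshold <= 0 || fdr_threshold > 1)
    stop("'fdr_threshold' must be in (0, 1]")
  if (!is.null(logger_pseudocount) &&
      (!is.numeric(logger_pseudocount) || length(logger_pseudocount) != 1L ||
       logger_pseudocount <= 0))
    stop("'logger_pseudocount' must be a single positive number or NULL")
  structure(list(dr_threshold = dr_threshold,
                 fdr_threshold = fdr_threshold,
                 logger_pseudocount = logger_pseudocount),
            class = "de_params")
}

#' @export
print.de_params <- function(x, ...) {
  cat(sprintf(
    "de_params: DR threshold %g, FDR threshold %g, logGER pseudocount %s\n",
    x$dr_threshold, x$fdr_threshold,
    if (is.null(x$logger_pseudocount)) "1/(number of cells)"
    else format(x$logger_pseudocount)))
  invisible(x)
}

# materialize the per-dataset default pseudocount
resolve_logger_pc <- function(params, n_cells) {
  if (is.null(params$logger_pseudocount)) 1 / n_cells
  else params$logger_pseudocount
}

#' Detection-rate filter for a pairwise comparison
#'
#' A gene enters the test for a pair of clusters if it is detected in at
#' least `dr_threshold` of the cells of at least one of the two clusters.
#' Rarely detected genes carry little rank information and bias the
#' rank-sum test toward sparsely detected genes, so they are excluded.
#'
#' @param dr_a,dr_b named numeric vectors of per-gene detection rates for
#'   the two clusters (same gene universe).
#' @param dr_threshold detection-rate threshold (default 0.10).
#' @return Character vector of gene ids passing the filter.
#' @export
filter_genes_pairwise <- function(dr_a, dr_b, dr_threshold = 0.10) {
  if (length(dr_a) != length(dr_b) ||
      !identical(names(dr_a), names(dr_b)))
    stop("'dr_a' and 'dr_b' must cover the same genes in the same order")
  names(dr_a)[dr_a >= dr_threshold | dr_b >= dr_threshold]
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' The workhorse test for differential expression between two groups of
#' cells. Uses the exact null distribution when the combined sample size is
#' at most 50 and there are no ties; otherwise the tie-corrected normal
#' approximation with continuity correction. The result is symmetric in the
#' order of the groups, and invariant under monotone transforms of the data
#' (so it is the same on log-normalized and de-logged values).
#'
#' @param a,b numeric vectors of values for the two groups (non-empty).
#' @return Two-sided p-value in `[0, 1]`.
#' @examples
#' wilcoxon_pvalue(c(5, 6, 7), c(1, 2, 3))  # 2/20 = 0.1 by enumeration
#' @export
wilcoxon_pvalue <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty; comparison is untestable")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("non-finite values in rank-sum test input")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  if (!ties && na + nb <= 50L) {
    p <- if (W > na * nb / 2)
      2 * stats::pwilcox(W - 1, na, nb, lower.tail = FALSE)
    else
      2 * stats::pwilcox(W, na, nb)
    return(min(1, p))
  }
  wilcox_normal_p(W, r, na, nb)
}

# normal approximation with tie and continuity corrections, as in the
# conventional base-R two-sided test
wilcox_normal_p <- function(W, r, na, nb) {
  n <- na + nb
  z <- W - na * nb / 2
  tie_tab <- table(r)
  sigma2 <- (na * nb / 12) *
    ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- z - sign(z) * 0.5
  min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
}

# vectorized over genes: xa, xb are genes x cells blocks; returns one
# p-value per row, identical to wilcoxon_pvalue() row by row
wilcox_pvals_rows <- function(xa, xb) {
  vapply(seq_len(nrow(xa)),
         function(i) wilcoxon_pvalue(xa[i, ], xb[i, ]),
         numeric(1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values controlling the false discovery rate,
#' with input validation. Results are in the input order and capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must all be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pseudocount-corrected log2 gene expression ratio
#'
#' `log2((mean_a + pc) / (mean_b + pc))` on normalized-count means. The
#' pseudocount keeps the ratio finite when one group has zero mean. A
#' pseudocount of 1 compresses ratios between low-abundance means, while a
#' vanishing pseudocount (e.g. 1e-99) sends comparisons with zero far
#' outside the range of the data; the package default of one over the
#' number of cells — the smallest observable step in count data — avoids
#' both failure modes.
#'
#' @param mean_a,mean_b normalized-count means (>= 0); vectors recycle.
#' @param pc pseudocount (> 0).
#' @return log2 ratio(s), finite, antisymmetric under argument swap.
#' @export
calc_logGER <- function(mean_a, mean_b, pc) {
  if (any(pc <= 0)) stop("'pc' must be positive")
  if (any(mean_a < 0) || any(mean_b < 0))
    stop("means must be non-negative")
  log2((mean_a + pc) / (mean_b + pc))
}

#' Difference in detection rate
#'
#' The second effect size reported for pairwise comparisons: `dr_a - dr_b`,
#' in `[-1, 1]`. Detection rate differences are especially informative for
#' marker genes, which should be undetected outside the cells they mark.
#'
#' @param dr_a,dr_b detection rates in `[0, 1]`; vectors recycle.
#' @return Difference(s) in `[-1, 1]`.
#' @export
calc_dDR <- function(dr_a, dr_b) {
  if (any(dr_a < 0 | dr_a > 1) || any(dr_b < 0 | dr_b > 1))
    stop("detection rates must be in [0, 1]")
  dr_a - dr_b
}

# guard for pair keys: labels may not contain the dash separator
check_label_chars <- function(s) {
  bad <- grepl("-", cluster_names(s), fixed = TRUE)
  if (any(bad))
    stop("cluster labels may not contain '-' (reserved for pair keys): ",
         paste(cluster_names(s)[bad], collapse = ", "))
}

#' Differential expression of each cluster versus the rest
#'
#' For every cluster, tests each gene between that cluster's cells and all
#' remaining cells pooled. Genes enter the test if their detection rate
#' reaches `dr_threshold` in the cluster or in the pooled rest; p-values
#' come from the Wilcoxon rank-sum test and are BH-adjusted within each
#' cluster's tested set. The log2 expression ratio (cluster over rest) is
#' reported for every gene, tested or not.
#'
#' @param m a [norm_matrix()].
#' @param s a [cluster_solution()] with at least two clusters.
#' @param stats optional precomputed [compute_cluster_gene_stats()] result.
#' @param params a [de_params()] object.
#' @return Named list (one element per cluster) of data frames with
#'   rownames = gene ids and columns `logGER`, `p_value`, `FDR`, `tested`.
#'   `p_value` and `FDR` are `NA` for untested genes.
#' @export
calc_de_vs_rest <- function(m, s, stats = NULL, params = de_params()) {
  stopifnot(inherits(m, "norm_matrix"), inherits(s, "cluster_solution"))
  s <- align_solution(s, m)
  if (n_clusters(s) < 2L)
    stop("differential expression requires at least two clusters")
  check_label_chars(s)
  if (is.null(stats)) stats <- compute_cluster_gene_stats(m, s)
  x <- delog_matrix(m)
  pc <- resolve_logger_pc(params, ncol(x))
  out <- lapply(cluster_names(s), function(cl) {
    in_cl <- s$labels == cl
    rest_stats <- gene_stats_from_counts(x[, !in_cl, drop = FALSE])
    de_table_for_groups(x[, in_cl, drop = FALSE],
                        x[, !in_cl, drop = FALSE],
                        stats[[cl]], rest_stats, params, pc,
                        with_dDR = FALSE)
  })
  names(out) <- cluster_names(s)
  structure(out, class = "de_vs_rest", solution_id = s$solution_id)
}

#' All pairwise differential expression between clusters
#'
#' Tests every unordered pair of clusters. Each pair gets its own
#' detection-rate filter and its own BH adjustment over the pair's tested
#' genes. Effect sizes `logGER` and `dDR` are reported for all genes and
#' are oriented first-named-cluster minus second; list elements are keyed
#' `"A-B"` with cluster names in level order.
#'
#' @inheritParams calc_de_vs_rest
#' @return Named list with one data frame per unordered pair (columns
#'   `logGER`, `dDR`, `p_value`, `FDR`, `tested`); each element carries a
#'   `"pair"` attribute with the two cluster names in key order.
#' @export
calc_de_combn <- function(m, s, stats = NULL, params = de_params()) {
  stopifnot(inherits(m, "norm_matrix"), inherits(s, "cluster_solution"))
  s <- align_solution(s, m)
  if (n_clusters(s) < 2L)
    stop("pairwise differential expression requires at least two clusters")
  check_label_chars(s)
  if (is.null(stats)) stats <- compute_cluster_gene_stats(m, s)
  x <- delog_matrix(m)
  pc <- resolve_logger_pc(params, ncol(x))
  cls <- cluster_names(s)
  pairs <- utils::combn(cls, 2L, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    tab <- de_table_for_groups(x[, s$labels == pr[1L], drop = FALSE],
                               x[, s$labels == pr[2L], drop = FALSE],
                               stats[[pr[1L]]], stats[[pr[2L]]],
                               params, pc, with_dDR = TRUE)
    attr(tab, "pair") <- pr
    tab
  })
  names(out) <- vapply(pairs, paste, character(1), collapse = "-")
  structure(out, class = "de_combn", solution_id = s$solution_id)
}

# shared worker: one comparison between two cell groups with known stats
de_table_for_groups <- function(xa, xb, stats_a, stats_b, params, pc,
                                with_dDR = TRUE) {
  genes <- rownames(xa)
  tested_ids <- filter_genes_pairwise(
    stats::setNames(stats_a$DR, genes),
    stats::setNames(stats_b$DR, genes),
    params$dr_threshold)
  tested <- genes %in% tested_ids
  p <- rep(NA_real_, length(genes))
  fdr <- rep(NA_real_, length(genes))
  if (any(tested)) {
    p[tested] <- wilcox_pvals_rows(xa[tested, , drop = FALSE],
                                   xb[tested, , drop = FALSE])
    fdr[tested] <- bh_adjust(p[tested])
  }
  tab <- data.frame(
    logGER = calc_logGER(stats_a$MGE, stats_b$MGE, pc),
    p_value = p, FDR = fdr, tested = tested,
    row.names = genes)
  if (with_dDR)
    tab <- cbind(tab[, "logGER", drop = FALSE],
                 dDR = calc_dDR(stats_a$DR, stats_b$DR),
                 tab[, c("p_value", "FDR", "tested")])
  tab
}
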