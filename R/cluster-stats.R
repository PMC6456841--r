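#' Construct a cluster solution
#'
#' A cluster solution is one partition of the cells, typically produced by a
#' clustering algorithm at one parameterization. Labels are always treated as
#' text categories: numeric-looking labels are not coerced, so `"1"` and
#' `"01"` remain distinct.
#'
#' @param labels vector or factor of per-cell cluster labels.
#' @param cell_ids character vector of cell identifiers, one per label.
#'   Defaults to `names(labels)`.
#' @param solution_id short name for this solution (e.g. `"res.0.8"`).
#' @return An object of class `"cluster_solution"`: list with `solution_id`
#'   and `labels`, a named factor (names are cell ids).
#' @export
cluster_solution <- function(labels, cell_ids = names(labels),
                             solution_id = "solution") {
  if (is.null(cell_ids))
    stop("cell identifiers are required (as 'cell_ids' or names of 'labels')")
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != length(labels))
    stop("'cell_ids' and 'labels' differ in length")
  if (anyDuplicated(cell_ids))
    stop("duplicated cell identifiers in cluster solution")
  if (anyNA(labels))
    stop("missing cluster label for cell(s): ",
         paste(utils::head(cell_ids[is.na(labels)], 5L), collapse = ", "))
  f <- factor(as.character(labels))
  if (nlevels(f) < 1L) stop("cluster solution has no clusters")
  names(f) <- cell_ids
  structure(list(solution_id = as.character(solution_id), labels = f),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution '%s': %d cells in %d clusters\n",
              x$solution_id, length(x$labels), nlevels(x$labels)))
  print(table(x$labels))
  invisible(x)
}

cluster_names <- function(s) levels(s$labels)
n_clusters <- function(s) nlevels(s$labels)

# reorder labels to the matrix's cell order; errors on mismatched cell sets
align_solution <- function(s, m) {
  cells <- cell_ids(m)
  if (length(s$labels) != length(cells) ||
      !setequal(names(s$labels), cells))
    stop(sprintf(
      "cluster solution '%s' does not cover the same cells as the matrix",
      s$solution_id))
  s$labels <- s$labels[cells]
  s
}

#' Warn about clusters too small to test
#'
#' Differential expression between clusters is meaningless for clusters of
#' one or two cells; this flags any cluster below `min_cells` so the user can
#' reconsider the solution before spending compute on it. Purely advisory:
#' nothing is modified or dropped.
#'
#' @param s a [cluster_solution()].
#' @param min_cells smallest cluster size considered testable (default 3).
#' @return Character vector of warning messages (empty when all clusters are
#'   large enough).
#' @export
validate_solution <- function(s, min_cells = 3L) {
  stopifnot(inherits(s, "cluster_solution"))
  sizes <- table(s$labels)
  small <- sizes[sizes < min_cells]
  if (length(small) == 0L) return(character(0))
  sprintf("cluster '%s' has %d cell(s), fewer than min_cells = %d",
          names(small), as.integer(small), as.integer(min_cells))
}

#' Per-cluster gene statistics on the normalized-count scale
#'
#' For every cluster and gene, computes the three summary statistics that
#' drive downstream filtering, effect sizes and display:
#' \describe{
#'   \item{DR}{detection rate — proportion of the cluster's cells with a
#'     non-zero expression value.}
#'   \item{MDGE}{mean detected gene expression — mean normalized count over
#'     only the cells in which the gene was detected (0 when undetected).}
#'   \item{MGE}{mean gene expression — mean normalized count over all cells
#'     of the cluster.}
#' }
#' All three are computed on the de-logged scale (see [delog_matrix()]), and
#' satisfy the identity `MGE = DR * MDGE` exactly.
#'
#' @param m a [norm_matrix()].
#' @param s a [cluster_solution()] covering the same cells.
#' @return An object of class `"cluster_gene_stats"`: a named list (one
#'   element per cluster) of data frames with rownames = gene ids and
#'   columns `DR`, `MDGE`, `MGE`.
#' @examples
#' x <- matrix(log2(c(0, 0, 2, 4) + 1), 1, 4,
#'             dimnames = list("g1", paste0("c", 1:4)))
#' s <- cluster_solution(rep("A", 4), paste0("c", 1:4))
#' compute_cluster_gene_stats(norm_matrix(x), s)[["A"]]
#' @export
compute_cluster_gene_stats <- function(m, s) {
  stopifnot(inherits(m, "norm_matrix"), inherits(s, "cluster_solution"))
  s <- align_solution(s, m)
  x <- delog_matrix(m)
  out <- lapply(cluster_names(s), function(cl) {
    xc <- x[, s$labels == cl, drop = FALSE]
    gene_stats_from_counts(xc)
  })
  names(out) <- cluster_names(s)
  structure(out, class = "cluster_gene_stats",
            solution_id = s$solution_id)
}

# statistics for one block of de-logged values (genes x cells)
gene_stats_from_counts <- function(xc) {
  n <- ncol(xc)
  det <- xc > 0
  ndet <- rowSums(det)
  DR <- ndet / n
  total <- rowSums(xc)
  MDGE <- ifelse(ndet > 0, total / ndet, 0)
  MGE <- total / n
  data.frame(DR = DR, MDGE = MDGE, MGE = MGE,
             row.names = rownames(xc))
}

#' @export
print.cluster_gene_stats <- function(x, ...) {
  cat(sprintf(
    "cluster_gene_stats for solution '%s': %d clusters x %d genes\n",
    attr(x, "solution_id"), length(x), nrow(x[[1L]])))
  invisible(x)
}
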