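#' Count significant genes in a pairwise DE table
#'
#' Counts genes at `FDR < fdr_threshold` in one pairwise comparison table,
#' either in both directions or only those positively differentially
#' expressed toward a query cluster (effect size oriented so that the query
#' cluster's side is positive).
#'
#' @param pair_table one element of a [calc_de_combn()] result.
#' @param fdr_threshold FDR significance threshold.
#' @param direction `"both"` (any sign) or `"positive"` (toward `query`).
#' @param query cluster name the positive direction refers to; required for
#'   `direction = "positive"`. Must be one of the table's pair.
#' @return Integer count (>= 0).
#' @export
count_significant_genes <- function(pair_table, fdr_threshold = 0.05,
                                    direction = c("both", "positive"),
                                    query = NULL) {
  direction <- match.arg(direction)
  sig <- !is.na(pair_table$FDR) & pair_table$FDR < fdr_threshold
  if (direction == "both") return(sum(sig))
  sgn <- orient_sign(pair_table, query)
  sum(sig & sgn * pair_table$logGER > 0)
}

# +1 if the query cluster is the first name of the pair key, -1 if second
orient_sign <- function(pair_table, query) {
  pr <- attr(pair_table, "pair")
  if (is.null(pr))
    stop("pairwise table lacks its 'pair' attribute")
  if (is.null(query) || !query %in% pr)
    stop("'query' must name one cluster of the pair ",
         paste(pr, collapse = "-"))
  if (query == pr[1L]) 1 else -1
}

pairs_involving <- function(combn, cl) {
  keep <- vapply(combn, function(tab) cl %in% attr(tab, "pair"),
                 logical(1))
  combn[keep]
}

#' Nearest neighbouring cluster by differential expression
#'
#' The nearest neighbour of a cluster is the other cluster with the fewest
#' significantly differentially expressed genes between them (counted in
#' both directions) — the cluster it is hardest to distinguish from. Ties
#' are broken by cluster-name sort order. The relation is not forced to be
#' symmetric.
#'
#' @param combn a [calc_de_combn()] result.
#' @param params a [de_params()]; only `fdr_threshold` is used.
#' @return Named character vector: `neighbour[cluster]` is the name of its
#'   nearest neighbour.
#' @export
find_nearest_neighbors <- function(combn, params = de_params()) {
  stopifnot(inherits(combn, "de_combn"))
  cls <- sort(unique(unlist(lapply(combn, attr, "pair"))))
  if (length(cls) < 2L) stop("need at least two clusters")
  out <- vapply(cls, function(cl) {
    tabs <- pairs_involving(combn, cl)
    others <- vapply(tabs, function(tab) {
      pr <- attr(tab, "pair"); pr[pr != cl]
    }, character(1))
    counts <- vapply(tabs, count_significant_genes,
                     integer(1) + 0, fdr_threshold = params$fdr_threshold,
                     direction = "both")
    ord <- order(counts, others)      # ties -> name order
    others[ord[1L]]
  }, character(1))
  names(out) <- cls
  out
}

#' Positively DE genes versus the nearest neighbouring cluster
#'
#' For each cluster, the set of genes significantly positively
#' differentially expressed (FDR below threshold, effect toward the
#' cluster) against its nearest neighbour. A cluster with an empty set is
#' statistically inseparable from its neighbour — the signature of
#' over-clustering that drives the stop-on-loss rule.
#'
#' @param scv an `"scv"` object from [calc_scv()], or a [calc_de_combn()]
#'   result.
#' @param fdr_threshold FDR significance threshold (default from the scv's
#'   stored params, else 0.05).
#' @return Named list of character vectors of gene ids, one per cluster.
#' @export
de_neighb <- function(scv, fdr_threshold = NULL) {
  combn <- as_de_combn(scv)
  thr <- resolve_fdr(scv, fdr_threshold)
  nb <- find_nearest_neighbors(combn, de_params(fdr_threshold = thr))
  out <- lapply(names(nb), function(cl) {
    key <- pair_key_for(combn, cl, nb[[cl]])
    positive_genes(combn[[key]], thr, cl)
  })
  names(out) <- names(nb)
  out
}

#' Marker genes: positively DE against every other cluster
#'
#' A gene is a marker of cluster `c` if it is significantly positively
#' differentially expressed toward `c` in the pairwise comparison with
#' every other cluster. This is the stricter of the two granularity
#' criteria: it guarantees each cluster a gene signature unique against
#' all others, so `de_marker(c)` is always a subset of [de_neighb()]'s set.
#'
#' @inheritParams de_neighb
#' @return Named list of character vectors of gene ids, one per cluster.
#' @export
de_marker <- function(scv, fdr_threshold = NULL) {
  combn <- as_de_combn(scv)
  thr <- resolve_fdr(scv, fdr_threshold)
  cls <- sort(unique(unlist(lapply(combn, attr, "pair"))))
  out <- lapply(cls, function(cl) {
    sets <- lapply(pairs_involving(combn, cl), positive_genes,
                   fdr_threshold = thr, query = cl)
    Reduce(intersect, sets)
  })
  names(out) <- cls
  out
}

positive_genes <- function(pair_table, fdr_threshold, query) {
  sgn <- orient_sign(pair_table, query)
  sig <- !is.na(pair_table$FDR) & pair_table$FDR < fdr_threshold &
    sgn * pair_table$logGER > 0
  rownames(pair_table)[sig]
}

pair_key_for <- function(combn, a, b) {
  k1 <- paste(a, b, sep = "-"); k2 <- paste(b, a, sep = "-")
  if (k1 %in% names(combn)) k1 else k2
}

as_de_combn <- function(x) {
  if (inherits(x, "de_combn")) return(x)
  if (inherits(x, "scv")) {
    if (is.null(x$de_combn))
      stop("this scv has no pairwise results (single-cluster solution?)")
    return(x$de_combn)
  }
  stop("expected an 'scv' or 'de_combn' object")
}

resolve_fdr <- function(x, fdr_threshold) {
  if (!is.null(fdr_threshold)) return(fdr_threshold)
  if (inherits(x, "scv")) return(x$params$fdr_threshold)
  0.05
}

#' Substitute externally computed differential expression results
#'
#' The assessment logic only needs per-comparison tables carrying an
#' effect size, a p-value and an FDR, so results from any test method
#' (MAST, limma, a model-based scRNA-seq test) can replace the built-in
#' Wilcoxon tables wholesale. Tables are schema-validated — required
#' columns, value ranges, gene universe, pair keys — but never
#' recomputed.
#'
#' @param scv an `"scv"` object.
#' @param de_vs_rest optional named list (cluster -> data frame with
#'   rownames = gene ids and columns `logGER`, `p_value`, `FDR`,
#'   `tested`) replacing the vs-rest slot.
#' @param de_combn optional named list (`"A-B"` pair key -> data frame,
#'   additionally with `dDR`) replacing the pairwise slot.
#' @return The scv with the replaced slot(s).
#' @export
set_de_results <- function(scv, de_vs_rest = NULL, de_combn = NULL) {
  stopifnot(inherits(scv, "scv"))
  cls <- cluster_names(scv$solution)
  genes <- rownames(scv$stats[[1L]])
  if (!is.null(de_vs_rest)) {
    if (!setequal(names(de_vs_rest), cls))
      stop("vs-rest tables must cover exactly the clusters: ",
           paste(cls, collapse = ", "))
    for (cl in names(de_vs_rest))
      check_de_schema(de_vs_rest[[cl]], genes, cl, need_dDR = FALSE)
    scv$de_vs_rest <- structure(de_vs_rest[cls], class = "de_vs_rest",
                                solution_id = scv$solution_id)
  }
  if (!is.null(de_combn)) {
    keys <- utils::combn(cls, 2L, paste, collapse = "-")
    if (!setequal(names(de_combn), keys))
      stop("pairwise tables must cover exactly the pair keys: ",
           paste(keys, collapse = ", "))
    de_combn <- de_combn[keys]
    for (key in keys) {
      check_de_schema(de_combn[[key]], genes, key, need_dDR = TRUE)
      attr(de_combn[[key]], "pair") <-
        strsplit(key, "-", fixed = TRUE)[[1L]]
    }
    scv$de_combn <- structure(de_combn, class = "de_combn",
                              solution_id = scv$solution_id)
  }
  scv
}

check_de_schema <- function(tab, genes, what, need_dDR) {
  need <- c("logGER", "p_value", "FDR", "tested",
            if (need_dDR) "dDR")
  missing_cols <- setdiff(need, colnames(tab))
  if (length(missing_cols))
    stop(sprintf("table '%s' lacks column(s): %s", what,
                 paste(missing_cols, collapse = ", ")))
  if (!setequal(rownames(tab), genes))
    stop(sprintf("table '%s' does not cover the gene universe", what))
  p <- tab$p_value[tab$tested]
  if (anyNA(p) || any(p < 0 | p > 1))
    stop(sprintf("table '%s' has invalid p-values for tested genes",
                 what))
  if (need_dDR && any(abs(tab$dDR) > 1 + 1e-9))
    stop(sprintf("table '%s' has dDR outside [-1, 1]", what))
  invisible(tab)
}

#' Silhouette widths on a reduced-dimension embedding
#'
#' For each cell `i`, the silhouette width is
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`, where `a(i)` is the mean
#' Euclidean distance to the other cells of its own cluster and `b(i)` is
#' the smallest mean distance to the cells of any other cluster. Widths lie
#' in `[-1, 1]`; positive means the cell sits closer to its own cluster.
#' Cells of singleton clusters, and degenerate cases with
#' `max(a, b) = 0`, get width 0. Coordinates are used exactly as given —
#' no axis reweighting is applied — so the user should supply the same
#' space that was used for clustering.
#'
#' @param embedding numeric cells x dims matrix with rownames = cell ids
#'   (a data frame is accepted).
#' @param s a [cluster_solution()] over the same cells (>= 2 clusters).
#' @return An object of class `"silhouette_widths"`: list with `cell`
#'   (data frame: cell, cluster, width), `cluster_means` (named vector)
#'   and `mean` (overall mean width).
#' @export
silhouette_widths <- function(embedding, s) {
  stopifnot(inherits(s, "cluster_solution"))
  embedding <- as.matrix(embedding)
  if (!is.numeric(embedding)) stop("embedding must be numeric")
  if (is.null(rownames(embedding)))
    stop("embedding must have cell ids as rownames")
  if (!setequal(rownames(embedding), names(s$labels)) ||
      nrow(embedding) != length(s$labels))
    stop("embedding rows do not match the cells of the cluster solution")
  if (n_clusters(s) < 2L)
    stop("silhouette requires at least two clusters")
  embedding <- embedding[names(s$labels), , drop = FALSE]
  lab <- s$labels
  d <- as.matrix(stats::dist(embedding))
  sizes <- table(lab)
  # mean distance from every cell to every cluster, via indicator algebra
  ind <- stats::model.matrix(~ lab - 1)
  colnames(ind) <- levels(lab)
  sums <- d %*% ind                       # cells x clusters distance sums
  n <- length(lab)
  width <- numeric(n)
  for (i in seq_len(n)) {
    cl <- as.character(lab[i])
    if (sizes[cl] == 1L) { width[i] <- 0; next }
    a <- sums[i, cl] / (sizes[cl] - 1L)
    others <- setdiff(levels(lab), cl)
    b <- min(sums[i, others] / as.numeric(sizes[others]))
    m <- max(a, b)
    width[i] <- if (m == 0) 0 else (b - a) / m
  }
  cell <- data.frame(cell = names(lab), cluster = as.character(lab),
                     width = width, stringsAsFactors = FALSE)
  cl_means <- tapply(width, lab, mean)
  structure(list(cell = cell,
                 cluster_means = stats::setNames(as.numeric(cl_means),
                                                 names(cl_means)),
                 mean = mean(width)),
            class = "silhouette_widths")
}

#' @export
print.silhouette_widths <- function(x, ...) {
  cat(sprintf("silhouette_widths: %d cells, mean width %.3f\n",
              nrow(x$cell), x$mean))
  invisible(x)
}

#' Assess one cluster solution
#'
#' The central fitting function: given the expression matrix and one
#' cluster solution, precomputes everything needed to judge and explore
#' that solution — per-cluster gene statistics, cluster-vs-rest and all
#' pairwise differential expression, and (when an embedding is supplied)
#' silhouette widths. The parameters used are stored alongside the
#' results, so an scv object is a self-contained, reproducible record of
#' the assessment.
#'
#' Single-cluster solutions are legal: they get gene statistics and
#' silhouette slots but no differential expression.
#'
#' @param m a [norm_matrix()].
#' @param s a [cluster_solution()] (or a named factor/vector of labels).
#' @param embedding optional cells x dims numeric matrix for silhouette.
#' @param params a [de_params()].
#' @return An object of class `"scv"`: list with `solution_id`, `solution`,
#'   `stats`, `de_vs_rest`, `de_combn`, `silhouette`, `params` (with the
#'   logGER pseudocount resolved to its numeric value), `n_cells`.
#' @examples
#' sim <- simulate_dataset(simulation_spec(n_clusters = 2,
#'   cells_per_cluster = 20, n_genes = 50, de_genes_per_cluster = 5))
#' fit <- calc_scv(sim$matrix, cluster_solution(sim$labels), sim$embedding)
#' summary(fit)
#' @export
calc_scv <- function(m, s, embedding = NULL, params = de_params()) {
  stopifnot(inherits(m, "norm_matrix"))
  if (!inherits(s, "cluster_solution")) s <- cluster_solution(s)
  s <- align_solution(s, m)
  w <- validate_solution(s)
  for (msg in w) warning(msg, call. = FALSE)
  params$logger_pseudocount <- resolve_logger_pc(params, ncol(m$values))
  stats <- compute_cluster_gene_stats(m, s)
  multi <- n_clusters(s) >= 2L
  sil <- if (!is.null(embedding) && multi) silhouette_widths(embedding, s)
  structure(list(
    solution_id = s$solution_id,
    solution = s,
    stats = stats,
    de_vs_rest = if (multi) calc_de_vs_rest(m, s, stats, params),
    de_combn = if (multi) calc_de_combn(m, s, stats, params),
    silhouette = sil,
    params = params,
    n_cells = ncol(m$values)),
    class = "scv")
}

#' @export
print.scv <- function(x, ...) {
  cat(sprintf("scv '%s': %d cells in %d clusters\n",
              x$solution_id, length(x$solution$labels),
              n_clusters(x$solution)))
  if (!is.null(x$de_combn)) {
    nb <- summarize_resolution(x)
    cat(sprintf("  neighbour-DE gene counts: %s\n",
                paste(sprintf("%s=%d", names(nb$neighb_counts),
                              nb$neighb_counts), collapse = " ")))
    cat(sprintf("  passed neighbour check: %s\n", nb$passed))
  }
  if (!is.null(x$silhouette))
    cat(sprintf("  mean silhouette width: %.3f\n", x$silhouette$mean))
  invisible(x)
}

#' @export
summary.scv <- function(object, ...) {
  sm <- summarize_resolution(object)
  cls <- cluster_names(object$solution)
  df <- data.frame(
    cluster = cls,
    n_cells = as.integer(table(object$solution$labels)[cls]),
    neighb_de = if (is.null(sm$neighb_counts)) NA_integer_
                else as.integer(sm$neighb_counts[cls]),
    markers = if (is.null(sm$marker_counts)) NA_integer_
              else as.integer(sm$marker_counts[cls]),
    mean_silhouette = if (is.null(object$silhouette)) NA_real_
                      else as.numeric(object$silhouette$cluster_means[cls]),
    row.names = NULL)
  structure(list(solution_id = object$solution_id, table = df,
                 passed = sm$passed), class = "summary.scv")
}

#' @export
print.summary.scv <- function(x, ...) {
  cat(sprintf("Assessment of cluster solution '%s'\n", x$solution_id))
  print(x$table, row.names = FALSE)
  cat(sprintf("passed neighbour check: %s\n", x$passed))
  invisible(x)
}

#' Summarize one assessed solution for the resolution table
#'
#' Collapses an scv object to the quantities used to compare resolutions:
#' the cluster count, per-cluster counts of positively DE genes versus the
#' nearest neighbour, per-cluster marker gene counts, the mean silhouette
#' width, and the pass/fail flag of the neighbour check (every cluster
#' must have at least one positively DE gene against its neighbour).
#'
#' @param scv an `"scv"` object.
#' @return List with `solution_id`, `n_clusters`, `neighb_counts`,
#'   `marker_counts`, `mean_silhouette`, `passed` (NA for single-cluster
#'   solutions, which have no neighbour pairs).
#' @export
summarize_resolution <- function(scv) {
  stopifnot(inherits(scv, "scv"))
  k <- n_clusters(scv$solution)
  if (k < 2L) {
    return(list(solution_id = scv$solution_id, n_clusters = k,
                neighb_counts = NULL, marker_counts = NULL,
                mean_silhouette =
                  if (is.null(scv$silhouette)) NA_real_
                  else scv$silhouette$mean,
                passed = NA))
  }
  nb <- lengths(de_neighb(scv))
  mk <- lengths(de_marker(scv))
  list(solution_id = scv$solution_id, n_clusters = k,
       neighb_counts = nb, marker_counts = mk,
       mean_silhouette = if (is.null(scv$silhouette)) NA_real_
                         else scv$silhouette$mean,
       passed = all(nb >= 1L))
}

#' Assess a series of cluster solutions at increasing resolution
#'
#' Processes cluster solutions in order of increasing cluster count
#' (stable on ties) and assesses each with [calc_scv()]. With
#' `stop_on_loss = TRUE`, the sweep halts after the first solution in
#' which some cluster has no positively DE gene against its nearest
#' neighbour: finer solutions would only split real populations further.
#' The failing solution is kept and flagged so it can be inspected.
#'
#' @param m a [norm_matrix()].
#' @param solutions list of [cluster_solution()] objects.
#' @param embedding optional cells x dims matrix for silhouette analysis.
#' @param params a [de_params()].
#' @param stop_on_loss halt after the first solution failing the
#'   neighbour check (default TRUE).
#' @return An object of class `"scv_sweep"`: list with `scvs` (named list
#'   of scv objects, in processing order), `summary` (one row per
#'   processed solution: solution_id, n_clusters, min/median neighbour-DE
#'   count, total markers, mean silhouette, passed), and `details` (named
#'   list of per-cluster count vectors).
#' @export
sweep_resolutions <- function(m, solutions, embedding = NULL,
                              params = de_params(), stop_on_loss = TRUE) {
  if (inherits(solutions, "cluster_solution")) solutions <- list(solutions)
  if (length(solutions) == 0L) stop("no cluster solutions supplied")
  ks <- vapply(solutions, function(s) nlevels(factor(as.character(
    if (inherits(s, "cluster_solution")) s$labels else s))), integer(1))
  solutions <- solutions[order(ks)]      # order() is stable on ties
  scvs <- list(); rows <- list(); details <- list()
  for (s in solutions) {
    fit <- calc_scv(m, s, embedding = embedding, params = params)
    sm <- summarize_resolution(fit)
    scvs[[fit$solution_id]] <- fit
    details[[fit$solution_id]] <- list(
      neighb_counts = sm$neighb_counts,
      marker_counts = sm$marker_counts)
    rows[[fit$solution_id]] <- data.frame(
      solution_id = sm$solution_id,
      n_clusters = sm$n_clusters,
      min_neighb_de = if (is.null(sm$neighb_counts)) NA_integer_
                      else as.integer(min(sm$neighb_counts)),
      median_neighb_de = if (is.null(sm$neighb_counts)) NA_real_
                         else stats::median(as.numeric(sm$neighb_counts)),
      total_markers = if (is.null(sm$marker_counts)) NA_integer_
                      else as.integer(sum(sm$marker_counts)),
      mean_silhouette = sm$mean_silhouette,
      passed = sm$passed,
      stringsAsFactors = FALSE)
    if (isTRUE(stop_on_loss) && isFALSE(sm$passed)) break
  }
  structure(list(scvs = scvs,
                 summary = do.call(rbind, c(rows, make.row.names = FALSE)),
                 details = details),
            class = "scv_sweep")
}

#' @export
print.scv_sweep <- function(x, ...) {
  cat(sprintf("scv_sweep: %d solution(s) assessed\n", length(x$scvs)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
plot.scv_sweep <- function(x, ...) {
  counts <- lapply(x$details, function(d)
    if (is.null(d$neighb_counts)) numeric(0)
    else as.numeric(d$neighb_counts))
  keep <- lengths(counts) > 0
  if (!any(keep)) {
    warning("no multi-cluster solutions to plot")
    return(invisible(x))
  }
  graphics::boxplot(counts[keep],
                    names = x$summary$n_clusters[keep],
                    xlab = "number of clusters",
                    ylab = "positively DE genes vs nearest neighbour",
                    ...)
  invisible(x)
}
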