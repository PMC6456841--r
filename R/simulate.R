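#' Specification for a synthetic cluster-structured dataset
#'
#' Parameters of the negative-binomial generator used to validate the
#' assessment pipeline. Each cluster owns an exclusive block of
#' differentially expressed genes whose mean is multiplied by
#' `effect_multiplier` in that cluster; all other genes share the
#' baseline mean. Defaults describe the reference validation scenario
#' used throughout the package's tests: 5 clusters of 40 cells, 500
#' genes, 10 exclusive DE genes per cluster at a 4-fold effect.
#'
#' @param n_clusters number of true clusters (>= 1).
#' @param cells_per_cluster cells per cluster.
#' @param n_genes total genes; must be >= `n_clusters * de_genes_per_cluster`.
#' @param de_genes_per_cluster exclusive DE genes per cluster.
#' @param effect_multiplier fold change of DE genes in their own cluster
#'   (1 = null data with no cluster structure).
#' @param baseline_mean mean count of a non-DE gene (> 0).
#' @param dispersion negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); > 0.
#' @param seed integer seed making the dataset reproducible.
#' @return An object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_clusters = 5L, cells_per_cluster = 40L,
                            n_genes = 500L, de_genes_per_cluster = 10L,
                            effect_multiplier = 4, baseline_mean = 1,
                            dispersion = 0.5, seed = 1L) {
  spec <- list(n_clusters = as.integer(n_clusters),
               cells_per_cluster = as.integer(cells_per_cluster),
               n_genes = as.integer(n_genes),
               de_genes_per_cluster = as.integer(de_genes_per_cluster),
               effect_multiplier = effect_multiplier,
               baseline_mean = baseline_mean,
               dispersion = dispersion,
               seed = as.integer(seed))
  if (spec$n_clusters < 1L) stop("'n_clusters' must be >= 1")
  if (spec$cells_per_cluster < 1L) stop("'cells_per_cluster' must be >= 1")
  if (spec$n_genes < 1L) stop("'n_genes' must be >= 1")
  if (spec$de_genes_per_cluster < 0L)
    stop("'de_genes_per_cluster' must be >= 0")
  if (spec$de_genes_per_cluster * spec$n_clusters > spec$n_genes)
    stop("n_clusters * de_genes_per_cluster exceeds n_genes")
  if (spec$effect_multiplier < 1)
    stop("'effect_multiplier' must be >= 1")
  if (spec$baseline_mean <= 0) stop("'baseline_mean' must be > 0")
  if (spec$dispersion <= 0) stop("'dispersion' must be > 0")
  structure(spec, class = "simulation_spec")
}

#' Simulate a sparse cluster-structured expression dataset
#'
#' Draws counts from a negative-binomial model (`size = 1/dispersion`),
#' multiplying the mean of each cluster's exclusive DE genes by the
#' effect size within that cluster. Counts are library-size normalized
#' (scaled to the median library size) and log2-transformed with a
#' pseudocount of 1, reproducing the conventional normalization the
#' assessment expects. Because counts are NB-distributed, detection rate
#' rises with expression magnitude, mirroring the dropout structure of
#' droplet-based scRNA-seq. A synthetic 2-D embedding (Gaussian blobs at
#' per-cluster centres on a circle) is included so silhouette analysis
#' can be exercised; it is generator ground truth, not a computed
#' dimensionality reduction.
#'
#' @param spec a [simulation_spec()].
#' @return An object of class `"sim_dataset"`: list with `counts` (sparse
#'   dgCMatrix, genes x cells), `labels` (named factor of true clusters),
#'   `matrix` (a [norm_matrix()] of the log-normalized data), `embedding`
#'   (cells x 2 matrix), `de_genes` (named list: true DE genes per
#'   cluster) and `spec`.
#' @export
simulate_dataset <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  K <- spec$n_clusters
  n_cells <- K * spec$cells_per_cluster
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  cells <- sprintf("cell%04d", seq_len(n_cells))
  clusters <- sprintf("c%d", seq_len(K))
  labels <- factor(rep(clusters, each = spec$cells_per_cluster),
                   levels = clusters)
  names(labels) <- cells
  de_genes <- lapply(seq_len(K), function(i) {
    if (spec$de_genes_per_cluster == 0L) return(character(0))
    idx <- ((i - 1L) * spec$de_genes_per_cluster + 1L):
      (i * spec$de_genes_per_cluster)
    genes[idx]
  })
  names(de_genes) <- clusters

  mu <- matrix(spec$baseline_mean, spec$n_genes, n_cells,
               dimnames = list(genes, cells))
  for (cl in clusters)
    mu[de_genes[[cl]], labels == cl] <-
      spec$baseline_mean * spec$effect_multiplier
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / spec$dispersion),
                   spec$n_genes, n_cells, dimnames = dimnames(mu))

  libsize <- colSums(counts)
  libsize[libsize == 0] <- 1          # empty cells: leave counts at zero
  sf <- libsize / stats::median(libsize)
  norm <- sweep(counts, 2L, sf, "/")
  logmat <- log2(norm + 1)

  centers <- cbind(cos(2 * pi * (seq_len(K) - 1) / K),
                   sin(2 * pi * (seq_len(K) - 1) / K)) * 5
  emb <- centers[as.integer(labels), , drop = FALSE] +
    matrix(stats::rnorm(2 * n_cells, sd = 0.5), n_cells, 2)
  dimnames(emb) <- list(cells, c("dim1", "dim2"))

  structure(list(counts = Matrix::Matrix(counts, sparse = TRUE),
                 labels = labels,
                 matrix = norm_matrix(logmat, log_base = 2,
                                      norm_pseudocount = 1),
                 embedding = emb,
                 de_genes = de_genes,
                 spec = spec),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "sim_dataset: %d genes x %d cells, %d clusters, %d DE genes/cluster (%gx), seed %d\n",
    nrow(x$counts), ncol(x$counts), x$spec$n_clusters,
    x$spec$de_genes_per_cluster, x$spec$effect_multiplier, x$spec$seed))
  invisible(x)
}

#' Build an under-/exact-/over-clustered solution series
#'
#' Produces cluster solutions at the requested cluster counts from a set
#' of true labels: counts below the true number merge true clusters by
#' balanced greedy pairing of the closest centroids (computed on the
#' de-logged data; the pair with the fewest already-merged members wins,
#' so merges stay balanced instead of chaining); the true count returns
#' the labels as given; counts above split clusters by random bisection
#' (largest cluster first, ties by name). The result is ordered by increasing
#' cluster count, ready for [sweep_resolutions()].
#'
#' @param labels named factor/vector of true cluster labels (>= 2
#'   clusters for merging).
#' @param data a [norm_matrix()] or numeric genes x cells matrix, needed
#'   when any requested count is below the true count.
#' @param ks integer vector of cluster counts; default
#'   `c(K - 1, K, K + 1)` (clipped to >= 1).
#' @param seed seed for the random bisections.
#' @return Named list of [cluster_solution()] objects (`"k<count>"`),
#'   ordered by increasing cluster count.
#' @export
build_resolution_series <- function(labels, data = NULL, ks = NULL,
                                    seed = 1L) {
  f <- factor(as.character(labels))
  names(f) <- names(labels)
  if (is.null(names(f))) stop("'labels' must carry cell ids as names")
  K <- nlevels(f)
  if (is.null(ks)) ks <- unique(pmax(1L, c(K - 1L, K, K + 1L)))
  ks <- sort(unique(as.integer(ks)))
  if (any(ks < 1L)) stop("cluster counts must be >= 1")
  if (any(ks > length(f))) stop("cannot have more clusters than cells")
  set.seed(as.integer(seed))
  cent <- NULL
  if (any(ks < K)) {
    if (is.null(data))
      stop("'data' is required to merge clusters (requested count below ",
           "the true cluster count)")
    x <- if (inherits(data, "norm_matrix")) delog_matrix(data)
         else as.matrix(data)
    cent <- t(vapply(levels(f),
                     function(cl) rowMeans(x[, f == cl, drop = FALSE]),
                     numeric(nrow(x))))
  }
  out <- lapply(ks, function(k) {
    lab <- if (k < K) merge_labels(f, cent, k)
           else if (k == K) stats::setNames(as.character(f), names(f))
           else split_labels(f, k - K)
    cluster_solution(lab, names(f), solution_id = sprintf("k%d", k))
  })
  names(out) <- sprintf("k%d", ks)
  out
}

# balanced greedy merging: repeatedly join the two closest clusters
# (Euclidean centroid distance), preferring the pair with the fewest
# combined member clusters so merges stay balanced rather than chaining
merge_labels <- function(f, cent, k) {
  groups <- as.list(rownames(cent))
  centroids <- cent
  sizes <- table(f)[rownames(cent)]
  while (length(groups) > k) {
    n <- length(groups)
    best <- NULL
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        cand <- c(length(groups[[i]]) + length(groups[[j]]),
                  sqrt(sum((centroids[i, ] - centroids[j, ])^2)))
        if (is.null(best) || cand[1] < best$key[1] ||
            (cand[1] == best$key[1] && cand[2] < best$key[2]))
          best <- list(key = cand, i = i, j = j)
      }
    }
    i <- best$i; j <- best$j
    w <- as.numeric(sizes[i] + sizes[j])
    centroids[i, ] <- (centroids[i, ] * as.numeric(sizes[i]) +
                         centroids[j, ] * as.numeric(sizes[j])) / w
    sizes[i] <- w
    groups[[i]] <- c(groups[[i]], groups[[j]])
    groups <- groups[-j]; centroids <- centroids[-j, , drop = FALSE]
    sizes <- sizes[-j]
  }
  merged <- stats::setNames(rep(NA_character_, nlevels(f)), levels(f))
  for (g in groups)
    merged[g] <- paste(sort(g), collapse = "+")
  stats::setNames(merged[as.character(f)], names(f))
}

# split clusters by random bisection, n_splits times
split_labels <- function(f, n_splits) {
  lab <- stats::setNames(as.character(f), names(f))
  for (i in seq_len(n_splits)) {
    sizes <- sort(table(lab), decreasing = TRUE)
    # largest first; table() sorts ties by name
    target <- names(sizes)[1L]
    cells <- names(lab)[lab == target]
    half <- sample(cells, floor(length(cells) / 2))
    lab[cells] <- paste0(target, "b")
    lab[half] <- paste0(target, "a")
  }
  lab
}

#' Grid of cluster mean abundances for the pseudocount demonstration
#'
#' A deterministic grid of per-cluster mean abundances of a single gene:
#' one zero-mean cluster plus evenly spaced means up to the maximum.
#' Used to demonstrate how the logGER pseudocount distorts expression
#' ratios, especially in comparisons with an undetected gene.
#'
#' @param n_clusters number of clusters (default 15).
#' @param max_mean largest mean abundance (default 50).
#' @return Strictly increasing numeric vector of length `n_clusters`
#'   starting at 0.
#' @export
pseudocount_grid <- function(n_clusters = 15L, max_mean = 50) {
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 2L) stop("'n_clusters' must be >= 2")
  c(0, seq(max_mean / (n_clusters - 1L), max_mean,
           length.out = n_clusters - 1L))
}

#' Pseudocount effect on pairwise expression ratios
#'
#' Evaluates [calc_logGER()] for every ordered pair of distinct grid
#' means under each candidate pseudocount, next to the true ratio
#' `log2(a/b)` (infinite when one mean is zero). A pseudocount of 1
#' compresses every finite ratio; a vanishing pseudocount (1e-99) sends
#' zero-mean comparisons beyond magnitude 300; one over the number of
#' cells keeps ratios close to truth while bounding the zero
#' comparisons.
#'
#' @param grid mean abundances, e.g. [pseudocount_grid()].
#' @param pseudocounts numeric vector of pseudocounts to evaluate;
#'   default `c(1, 1e-99, 1/1000)` (1000 being the notional number of
#'   cells in the simulated data).
#' @return Data frame with columns `mean_a`, `mean_b`, `pseudocount`,
#'   `true_logGER`, `logGER`.
#' @export
pseudocount_comparison <- function(grid = pseudocount_grid(),
                                   pseudocounts = c(1, 1e-99, 1 / 1000)) {
  if (any(grid < 0)) stop("grid means must be non-negative")
  idx <- expand.grid(a = seq_along(grid), b = seq_along(grid))
  idx <- idx[idx$a != idx$b, ]
  rows <- lapply(pseudocounts, function(pc) {
    a <- grid[idx$a]; b <- grid[idx$b]
    data.frame(mean_a = a, mean_b = b, pseudocount = pc,
               true_logGER = log2(a / b),
               logGER = calc_logGER(a, b, pc))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
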