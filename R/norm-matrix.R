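#' Construct a log-normalized expression matrix
#'
#' Wraps a genes x cells matrix of log-normalized expression values together
#' with the two pieces of metadata needed to recover the normalized-count
#' scale: the log base and the pseudocount added before the log transform.
#' Means of log-normalized data are misleading, so every downstream statistic
#' (detection rate, mean expression, expression ratios) is computed after
#' de-logging; getting these two numbers right is therefore essential.
#'
#' @param values numeric genes x cells matrix (base matrix or any
#'   \pkg{Matrix} class; coerced to a dense base matrix). Rows are genes,
#'   columns are cells.
#' @param gene_ids,cell_ids character vectors of unique row/column
#'   identifiers. Default to the dimnames of `values`.
#' @param log_base base of the log transform used in normalization
#'   (must be > 1). Most pipelines use 2; some use `exp(1)`.
#' @param norm_pseudocount pseudocount added before the log transform
#'   (>= 0), almost always 1.
#' @return An object of class `"norm_matrix"`: a list with elements
#'   `values`, `log_base`, `norm_pseudocount`.
#' @examples
#' x <- matrix(c(0, 1, 2, 0), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' m <- norm_matrix(x)
#' delog_matrix(m)
#' @export
norm_matrix <- function(values, gene_ids = rownames(values),
                        cell_ids = colnames(values),
                        log_base = 2, norm_pseudocount = 1) {
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x cells)")
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene and cell identifiers are required (as arguments or dimnames)")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("length of 'gene_ids' does not match the number of rows")
  if (length(cell_ids) != ncol(values))
    stop("length of 'cell_ids' does not match the number of columns")
  if (anyDuplicated(gene_ids))
    stop("duplicated gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("duplicated cell identifiers: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("'values' contains non-finite entries")
  if (!is.numeric(log_base) || length(log_base) != 1L || log_base <= 1)
    stop("'log_base' must be a single number > 1")
  if (!is.numeric(norm_pseudocount) || length(norm_pseudocount) != 1L ||
      norm_pseudocount < 0)
    stop("'norm_pseudocount' must be a single number >= 0")
  dimnames(values) <- list(gene_ids, cell_ids)
  m <- structure(list(values = values,
                      log_base = log_base,
                      norm_pseudocount = norm_pseudocount),
                 class = "norm_matrix")
  # de-logged values must land on the non-negative count scale
  dl <- m$log_base^m$values - m$norm_pseudocount
  bad <- dl < -1e-9
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "de-logged value is negative for gene '%s', cell '%s' (%.3g); %s",
      gene_ids[idx[1L]], cell_ids[idx[2L]], dl[idx[1L], idx[2L]],
      "check 'log_base' and 'norm_pseudocount'"))
  }
  m
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf(
    "norm_matrix: %d genes x %d cells (log base %g, pseudocount %g)\n",
    nrow(x$values), ncol(x$values), x$log_base, x$norm_pseudocount))
  invisible(x)
}

#' @export
dim.norm_matrix <- function(x) dim(x$values)

gene_ids <- function(m) rownames(m$values)
cell_ids <- function(m) colnames(m$values)

#' Undo the log transform of a normalized expression matrix
#'
#' Maps every stored value `v` to `log_base^v - norm_pseudocount`, recovering
#' the normalized-count scale on which means and detection rates are
#' meaningful. Values that land within `1e-9` below zero (floating-point
#' slack from the original transform) are clamped to exactly zero; anything
#' more negative is an error, since it indicates wrong metadata.
#'
#' @param m a [norm_matrix()] object.
#' @return A dense numeric genes x cells matrix of normalized counts (>= 0).
#' @export
delog_matrix <- function(m) {
  stopifnot(inherits(m, "norm_matrix"))
  x <- m$log_base^m$values - m$norm_pseudocount
  if (!all(is.finite(x))) {
    idx <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite de-logged value for gene '%s', cell '%s'",
                 rownames(x)[idx[1L]], colnames(x)[idx[2L]]))
  }
  bad <- x < -1e-9
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative de-logged value for gene '%s', cell '%s'",
                 rownames(x)[idx[1L]], colnames(x)[idx[2L]]))
  }
  x[x < 0] <- 0
  x
}

# inverse of delog_matrix, used for round-trip checks
relog_values <- function(x, log_base, norm_pseudocount) {
  log(x + norm_pseudocount, base = log_base)
}
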