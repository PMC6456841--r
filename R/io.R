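#' Read a log-normalized expression matrix
#'
#' Two on-disk layouts are supported, both yielding the canonical
#' genes x cells orientation:
#' \itemize{
#'   \item Matrix Market sparse triplet (`.mtx`, 1-based indices per the
#'     format standard) plus two plain-text id files, one gene id and one
#'     cell id per line. By default these are looked for next to the
#'     matrix as `<stem>_genes.txt` and `<stem>_cells.txt`.
#'   \item Dense TSV with a header of cell ids and gene ids in the first
#'     column.
#' }
#' Explicit zeros in a Matrix Market file are kept as zeros, i.e. treated
#' as undetected. Duplicate ids and dimension mismatches are rejected.
#'
#' @param path matrix file (`.mtx` or TSV).
#' @param gene_file,cell_file id files for the Matrix Market layout;
#'   defaults derived from `path`.
#' @param log_base,norm_pseudocount normalization metadata recorded on
#'   the returned object (see [norm_matrix()]).
#' @return A [norm_matrix()].
#' @export
read_expression_matrix <- function(path, gene_file = NULL, cell_file = NULL,
                                   log_base = 2, norm_pseudocount = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    if (is.null(gene_file)) gene_file <- paste0(stem, "_genes.txt")
    if (is.null(cell_file)) cell_file <- paste0(stem, "_cells.txt")
    for (f in c(gene_file, cell_file))
      if (!file.exists(f)) stop("missing id file: ", f)
    vals <- tryCatch(Matrix::readMM(path),
                     error = function(e)
                       stop("malformed Matrix Market file '", path, "': ",
                            conditionMessage(e)))
    genes <- readLines(gene_file)
    cells <- readLines(cell_file)
    if (nrow(vals) != length(genes))
      stop(sprintf("matrix has %d rows but %d gene ids", nrow(vals),
                   length(genes)))
    if (ncol(vals) != length(cells))
      stop(sprintf("matrix has %d columns but %d cell ids", ncol(vals),
                   length(cells)))
    m <- as.matrix(vals)
    dimnames(m) <- list(genes, cells)
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character")
    if (ncol(df) < 2L) stop("dense matrix TSV needs id column + data")
    genes <- df[[1L]]
    m <- as.matrix(df[, -1L, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "double")
    if (anyNA(m)) stop("non-numeric value in dense matrix TSV: ", path)
    rownames(m) <- genes
  }
  norm_matrix(m, log_base = log_base, norm_pseudocount = norm_pseudocount)
}

#' Write an expression matrix as dense TSV
#'
#' Inverse of the dense layout of [read_expression_matrix()]: gene ids in
#' the first column (`gene`), one column per cell.
#'
#' @param m a [norm_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(inherits(m, "norm_matrix"))
  df <- data.frame(gene = gene_ids(m), m$values, check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Write a matrix as Matrix Market triplets plus id files
#'
#' Writes `<path>` (`.mtx`), `<stem>_genes.txt` and `<stem>_cells.txt`,
#' the sparse layout accepted by [read_expression_matrix()].
#'
#' @param x numeric matrix or Matrix (genes x cells, with dimnames).
#' @param path output `.mtx` file.
#' @return `path`, invisibly.
#' @export
write_mtx <- function(x, path) {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("matrix must have gene and cell ids as dimnames")
  Matrix::writeMM(Matrix::Matrix(as.matrix(x), sparse = TRUE), path)
  stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
  writeLines(rownames(x), paste0(stem, "_genes.txt"))
  writeLines(colnames(x), paste0(stem, "_cells.txt"))
  invisible(path)
}

#' Read a table of cluster solutions
#'
#' TSV with cell ids in the first column and one column per cluster
#' solution. Labels are read as text and never coerced to numbers, so
#' `"1"` and `"01"` stay distinct.
#'
#' @param path TSV file.
#' @return Named list of [cluster_solution()] objects, one per column.
#' @export
read_cluster_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L)
    stop("cluster table needs a cell id column plus >= 1 solution column")
  cells <- df[[1L]]
  if (anyDuplicated(cells)) stop("duplicated cell ids in cluster table")
  empty <- df == ""
  if (any(empty)) {
    w <- which(empty, arr.ind = TRUE)[1L, ]
    stop(sprintf("missing cluster label for cell '%s' in solution '%s'",
                 cells[w[1L]], colnames(df)[w[2L]]))
  }
  out <- lapply(colnames(df)[-1L], function(col)
    cluster_solution(df[[col]], cells, solution_id = col))
  names(out) <- colnames(df)[-1L]
  out
}

#' Read a reduced-dimension embedding
#'
#' TSV with cell ids in the first column and numeric coordinate columns.
#' Coordinates are used exactly as stored (no reweighting); rows are
#' aligned to the expression matrix by cell id downstream.
#'
#' @param path TSV file.
#' @return Numeric cells x dims matrix with cell ids as rownames.
#' @export
read_embedding <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("embedding needs a cell id column + coordinates")
  cells <- df[[1L]]
  if (anyDuplicated(cells)) stop("duplicated cell ids in embedding")
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) stop("non-numeric coordinate in embedding: ", path)
  rownames(m) <- cells
  m
}

# deterministic TSV writer shared by all table exports
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

de_table_to_df <- function(tab) {
  cols <- intersect(c("logGER", "dDR", "p_value", "FDR", "tested"),
                    colnames(tab))
  df <- data.frame(gene = rownames(tab), tab[, cols, drop = FALSE],
                   row.names = NULL, stringsAsFactors = FALSE)
  df[order(df$gene), , drop = FALSE]
}

df_to_de_table <- function(df) {
  tab <- df[, setdiff(colnames(df), "gene"), drop = FALSE]
  rownames(tab) <- df$gene
  tab$tested <- as.logical(tab$tested)
  tab
}

#' Export differential expression tables as TSV
#'
#' Writes one TSV per comparison of an assessed solution (or cell-set
#' comparison): `vsrest_<cluster>.tsv` and `pairwise_<A>-<B>.tsv`, with
#' fixed column order (`gene`, `logGER`, `dDR` for pairwise, `p_value`,
#' `FDR`, `tested`) and rows sorted by gene id, so re-exports are
#' byte-identical.
#'
#' @param scv an `"scv"` object (including cell-set comparisons).
#' @param out_dir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_de_tables <- function(scv, out_dir) {
  stopifnot(inherits(scv, "scv"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (cl in names(scv$de_vs_rest)) {
    f <- file.path(out_dir, paste0("vsrest_", cl, ".tsv"))
    write_tsv(de_table_to_df(scv$de_vs_rest[[cl]]), f)
    files <- c(files, f)
  }
  for (key in names(scv$de_combn)) {
    f <- file.path(out_dir, paste0("pairwise_", key, ".tsv"))
    write_tsv(de_table_to_df(scv$de_combn[[key]]), f)
    files <- c(files, f)
  }
  invisible(files)
}

stats_to_df <- function(stats) {
  rows <- lapply(names(stats), function(cl)
    data.frame(cluster = cl, gene = rownames(stats[[cl]]),
               stats[[cl]], row.names = NULL, stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df[order(df$cluster, df$gene), , drop = FALSE]
}
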