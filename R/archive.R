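#' Save assessment results as an open archive
#'
#' Persists a full resolution sweep (and any saved cell-set comparisons)
#' as a directory of TSV tables plus a JSON manifest, so results are
#' shareable and readable without this package. The manifest records the
#' dataset hash, the testing parameters, the solutions present, the
#' saved default resolution and the saved comparisons; loading verifies
#' it against the files on disk. When `path` ends in `.tar.gz` or
#' `.tgz` the directory is packed into a single portable file with all
#' timestamps pinned, so identical runs produce byte-identical archives.
#'
#' @param x an `"scv_sweep"` from [sweep_resolutions()], a single
#'   `"scv"`, or a list of scv objects.
#' @param path target directory, or a `.tar.gz`/`.tgz` file.
#' @param matrix optional [norm_matrix()]; when given, a hash of the
#'   data is stored so archives can be matched to their dataset.
#' @param default_resolution optional solution id to record as the saved
#'   default; must name a stored solution.
#' @param comparisons optional named list of
#'   [compare_cell_sets()] results to store as pseudo-solutions.
#' @return `path`, invisibly.
#' @export
save_results_archive <- function(x, path, matrix = NULL,
                                 default_resolution = NULL,
                                 comparisons = NULL) {
  sweep <- as_sweep(x)
  if (!is.null(comparisons)) {
    if (is.null(names(comparisons)))
      names(comparisons) <- vapply(comparisons, `[[`, character(1),
                                   "solution_id")
    lapply(comparisons, function(cmp)
      stopifnot(inherits(cmp, "cell_set_comparison")))
  }
  if (!is.null(default_resolution) &&
      !default_resolution %in% names(sweep$scvs))
    stop("default_resolution '", default_resolution,
         "' is not among the stored solutions")
  as_tar <- grepl("\\.(tar\\.gz|tgz)$", path)
  dir <- if (as_tar) file.path(tempfile("archive"), "results") else path
  write_archive_dir(sweep, dir, matrix, default_resolution, comparisons)
  if (as_tar) pack_archive(dir, path)
  invisible(path)
}

as_sweep <- function(x) {
  if (inherits(x, "scv_sweep")) return(x)
  if (inherits(x, "scv")) x <- list(x)
  if (is.list(x) && all(vapply(x, inherits, logical(1), "scv"))) {
    rows <- lapply(x, function(fit) {
      sm <- summarize_resolution(fit)
      data.frame(solution_id = sm$solution_id, n_clusters = sm$n_clusters,
                 min_neighb_de = if (is.null(sm$neighb_counts)) NA_integer_
                                 else as.integer(min(sm$neighb_counts)),
                 median_neighb_de = if (is.null(sm$neighb_counts)) NA_real_
                   else stats::median(as.numeric(sm$neighb_counts)),
                 total_markers = if (is.null(sm$marker_counts)) NA_integer_
                                 else as.integer(sum(sm$marker_counts)),
                 mean_silhouette = sm$mean_silhouette,
                 passed = sm$passed, stringsAsFactors = FALSE)
    })
    details <- lapply(x, function(fit) {
      sm <- summarize_resolution(fit)
      list(neighb_counts = sm$neighb_counts,
           marker_counts = sm$marker_counts)
    })
    ids <- vapply(x, `[[`, character(1), "solution_id")
    names(x) <- ids; names(details) <- ids
    return(structure(list(scvs = x,
                          summary = do.call(rbind,
                            c(rows, make.row.names = FALSE)),
                          details = details),
                     class = "scv_sweep"))
  }
  stop("expected an scv_sweep, an scv, or a list of scv objects")
}

write_archive_dir <- function(sweep, dir, matrix, default_resolution,
                              comparisons) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sol_ids <- names(sweep$scvs)
  cmp_ids <- names(comparisons)
  first <- sweep$scvs[[1L]]
  manifest <- list(
    format = "clustgrain-archive-v1",
    dataset_hash = if (is.null(matrix)) "unavailable"
                   else hash_matrix(matrix),
    n_cells = first$n_cells,
    params = first$params[c("dr_threshold", "fdr_threshold",
                            "logger_pseudocount")],
    solutions = lapply(sol_ids, function(id) list(
      id = id,
      n_clusters = n_clusters(sweep$scvs[[id]]$solution),
      files = archive_solution_files(sweep$scvs[[id]]))),
    default_resolution = default_resolution,
    comparisons = lapply(cmp_ids, function(id) list(
      id = id, files = archive_solution_files(comparisons[[id]]))))
  for (id in sol_ids)
    write_solution_dir(sweep$scvs[[id]], file.path(dir, solution_dirname(id)))
  for (id in cmp_ids)
    write_solution_dir(comparisons[[id]],
                       file.path(dir, comparison_dirname(id)))
  write_tsv(sweep$summary, file.path(dir, "summary.tsv"))
  jsonlite::write_json(sweep$details, file.path(dir, "details.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

solution_dirname <- function(id) paste0("sol_", sanitize_id(id))
comparison_dirname <- function(id) paste0("cmp_", sanitize_id(id))
sanitize_id <- function(id) gsub("[^A-Za-z0-9._+-]", "_", id)

archive_solution_files <- function(scv) {
  files <- c("clusters.tsv", "stats.tsv")
  files <- c(files, paste0("vsrest_", names(scv$de_vs_rest), ".tsv"))
  files <- c(files, paste0("pairwise_", names(scv$de_combn), ".tsv"))
  if (!is.null(scv$silhouette)) files <- c(files, "silhouette.tsv")
  files
}

write_solution_dir <- function(scv, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(data.frame(cell = names(scv$solution$labels),
                       cluster = as.character(scv$solution$labels),
                       stringsAsFactors = FALSE),
            file.path(dir, "clusters.tsv"))
  write_tsv(stats_to_df(scv$stats), file.path(dir, "stats.tsv"))
  write_de_tables(scv, dir)
  if (!is.null(scv$silhouette))
    write_tsv(scv$silhouette$cell, file.path(dir, "silhouette.tsv"))
  invisible(dir)
}

hash_matrix <- function(m) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(c(gene_ids(m), cell_ids(m),
               format(c(m$log_base, m$norm_pseudocount, m$values),
                      digits = 15, trim = TRUE)), f)
  unname(tools::md5sum(f))
}

# pack a directory into a tar.gz with pinned timestamps so identical
# contents give identical bytes
pack_archive <- function(dir, tarfile) {
  files <- sort(list.files(dir, recursive = TRUE, all.files = TRUE))
  dirs <- setdiff(sort(list.dirs(dir, full.names = FALSE)), "")
  epoch <- as.POSIXct("2000-01-01 00:00:00", tz = "UTC")
  for (f in c(".", dirs, files))
    Sys.setFileTime(file.path(dir, f), epoch)
  if (!grepl("^(/|[A-Za-z]:)", tarfile))
    tarfile <- file.path(normalizePath("."), tarfile)
  old <- setwd(dir)
  on.exit(setwd(old))
  utils::tar(tarfile, files = files, compression = "gzip",
             tar = "internal")
  invisible(tarfile)
}

#' Load a results archive
#'
#' Reads an archive written by [save_results_archive()] (directory or
#' `.tar.gz`), verifies every table listed in the manifest is present,
#' and reconstructs the solutions' tables: cluster assignments, gene
#' statistics, vs-rest and pairwise differential expression (as
#' `"de_combn"` objects usable by [de_marker()], [de_neighb()] and
#' [find_nearest_neighbors()]), and silhouette widths.
#'
#' @param path archive directory or `.tar.gz`/`.tgz` file.
#' @return An object of class `"results_archive"`: list with `manifest`,
#'   `summary`, `details`, `solutions` and `comparisons`.
#' @export
load_results_archive <- function(path) {
  if (!file.exists(path)) stop("no such archive: ", path)
  dir <- path
  if (!dir.exists(path)) {
    dir <- tempfile("archive")
    utils::untar(path, exdir = dir)
  }
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("archive has no manifest.json")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  # an unset default serializes as an empty object; normalize to NULL
  if (!is.character(manifest$default_resolution) ||
      length(manifest$default_resolution) != 1L)
    manifest$default_resolution <- NULL
  solutions <- lapply(manifest$solutions, function(sol)
    read_solution_dir(file.path(dir, solution_dirname(sol$id)), sol))
  names(solutions) <- vapply(manifest$solutions, `[[`, character(1), "id")
  comparisons <- lapply(manifest$comparisons, function(cmp)
    read_solution_dir(file.path(dir, comparison_dirname(cmp$id)), cmp))
  names(comparisons) <- vapply(manifest$comparisons, `[[`,
                               character(1), "id")
  if (!is.null(manifest$default_resolution) &&
      !manifest$default_resolution %in% names(solutions))
    stop("manifest names default resolution '",
         manifest$default_resolution, "' but no such solution is stored")
  structure(list(
    manifest = manifest,
    summary = utils::read.delim(file.path(dir, "summary.tsv")),
    details = jsonlite::read_json(file.path(dir, "details.json"),
                                  simplifyVector = TRUE),
    solutions = solutions,
    comparisons = comparisons),
    class = "results_archive")
}

read_solution_dir <- function(dir, sol) {
  for (f in sol$files)
    if (!file.exists(file.path(dir, f)))
      stop(sprintf("archive is missing table '%s' for solution '%s'",
                   f, sol$id))
  clusters <- utils::read.delim(file.path(dir, "clusters.tsv"),
                                colClasses = "character")
  stats_df <- utils::read.delim(file.path(dir, "stats.tsv"),
                                colClasses = c(cluster = "character",
                                               gene = "character"))
  stats <- lapply(split(stats_df, stats_df$cluster), function(d) {
    rownames(d) <- d$gene
    d[, c("DR", "MDGE", "MGE")]
  })
  stats <- structure(stats[unique(stats_df$cluster)],
                     class = "cluster_gene_stats", solution_id = sol$id)
  vs_files <- grep("^vsrest_", sol$files, value = TRUE)
  vs <- lapply(vs_files, function(f)
    df_to_de_table(utils::read.delim(file.path(dir, f),
                                     colClasses = c(gene = "character"))))
  names(vs) <- sub("^vsrest_(.*)\\.tsv$", "\\1", vs_files)
  pw_files <- grep("^pairwise_", sol$files, value = TRUE)
  pw <- lapply(pw_files, function(f) {
    tab <- df_to_de_table(utils::read.delim(file.path(dir, f),
                                            colClasses = c(gene = "character")))
    key <- sub("^pairwise_(.*)\\.tsv$", "\\1", f)
    attr(tab, "pair") <- strsplit(key, "-", fixed = TRUE)[[1L]]
    tab
  })
  names(pw) <- sub("^pairwise_(.*)\\.tsv$", "\\1", pw_files)
  sil <- if ("silhouette.tsv" %in% sol$files)
    utils::read.delim(file.path(dir, "silhouette.tsv"),
                      colClasses = c(cell = "character",
                                     cluster = "character"))
  list(id = sol$id,
       clusters = clusters,
       stats = stats,
       de_vs_rest = if (length(vs))
         structure(vs, class = "de_vs_rest", solution_id = sol$id),
       de_combn = if (length(pw))
         structure(pw, class = "de_combn", solution_id = sol$id),
       silhouette = sil)
}

#' @export
print.results_archive <- function(x, ...) {
  cat(sprintf(
    "results_archive: %d solution(s), %d comparison(s)%s\n",
    length(x$solutions), length(x$comparisons),
    if (is.null(x$manifest$default_resolution)) ""
    else sprintf(", default '%s'", x$manifest$default_resolution)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
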