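#' Render static assessment figures
#'
#' Writes the package's standard figures as vector graphics:
#' \itemize{
#'   \item `assessment.<ext>` — boxplots of per-cluster neighbour-DE gene
#'     counts, one box per solution, arranged by cluster count;
#'   \item `silhouette_<id>.<ext>` — per-solution silhouette bar plot,
#'     cells grouped by cluster;
#'   \item `dotplot_<id>.<ext>` — marker-gene dot plot (dot size =
#'     detection rate, shade = mean detected expression);
#'   \item `scatter_<id>.<ext>` — per-cluster DR versus MDGE scatter
#'     (one page per cluster).
#' }
#' The function returns the numeric tables behind each figure so the
#' plotted numbers can be checked; aesthetics are deliberately plain
#' base graphics.
#'
#' @param x an `"scv_sweep"` (or anything [save_results_archive()]
#'   accepts).
#' @param out_dir output directory (created if needed).
#' @param format `"pdf"` (default) or `"svg"`.
#' @param top_n marker genes per cluster shown in the dot plot.
#' @return Invisibly, a list with `files` (paths written) and `data`
#'   (named list of the data frames plotted).
#' @export
render_static_figures <- function(x, out_dir, format = c("pdf", "svg"),
                                  top_n = 10L) {
  format <- match.arg(format)
  sweep <- as_sweep(x)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dev_open <- function(f) {
    if (format == "pdf") grDevices::pdf(f, width = 8, height = 6,
                                        onefile = TRUE)
    else grDevices::svg(f, width = 8, height = 6)
  }
  files <- character(0); data <- list()

  f <- file.path(out_dir, paste0("assessment.", format))
  counts <- lapply(sweep$details, function(d)
    if (is.null(d$neighb_counts)) numeric(0)
    else as.numeric(d$neighb_counts))
  dev_open(f)
  keep <- lengths(counts) > 0
  if (any(keep)) {
    graphics::boxplot(counts[keep], names = sweep$summary$n_clusters[keep],
                      xlab = "number of clusters",
                      ylab = "positively DE genes vs nearest neighbour",
                      main = "Cluster resolution assessment")
  } else {
    plot_empty("no multi-cluster solutions")
  }
  grDevices::dev.off()
  files <- c(files, f)
  data$assessment <- sweep$summary

  for (id in names(sweep$scvs)) {
    fit <- sweep$scvs[[id]]
    if (!is.null(fit$silhouette)) {
      f <- file.path(out_dir, paste0("silhouette_", sanitize_id(id), ".",
                                     format))
      sil <- fit$silhouette$cell
      ord <- order(sil$cluster, -sil$width)
      dev_open(f)
      graphics::barplot(rev(sil$width[ord]), horiz = TRUE, border = NA,
                        col = factor(rev(sil$cluster[ord])),
                        xlab = "silhouette width", main = id)
      grDevices::dev.off()
      files <- c(files, f)
      data[[paste0("silhouette_", id)]] <- sil[ord, ]
    }
    if (!is.null(fit$de_combn)) {
      mk <- de_marker(fit)
      dp <- dotplot_data(fit, mk, top_n)
      f <- file.path(out_dir, paste0("dotplot_", sanitize_id(id), ".",
                                     format))
      dev_open(f)
      plot_dotplot(dp, id, sum(lengths(mk)))
      grDevices::dev.off()
      files <- c(files, f)
      data[[paste0("dotplot_", id)]] <- dp
    }
    f <- file.path(out_dir, paste0("scatter_", sanitize_id(id), ".",
                                   format))
    dev_open(f)
    for (cl in names(fit$stats)) {
      st <- fit$stats[[cl]]
      graphics::plot(st$DR, st$MDGE, pch = 16, cex = 0.6,
                     col = grDevices::grey(0.3, alpha = 0.6),
                     xlab = "detection rate",
                     ylab = "mean detected expression",
                     main = sprintf("%s - cluster %s", id, cl))
    }
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(list(files = files, data = data))
}

plot_empty <- function(msg) {
  graphics::plot.new()
  graphics::text(0.5, 0.5, msg)
}

# long table of (cluster, gene, DR, MDGE) for the top marker genes
dotplot_data <- function(fit, markers, top_n) {
  genes <- unique(unlist(lapply(names(markers), function(cl) {
    g <- markers[[cl]]
    if (length(g) == 0L) return(character(0))
    r <- rank_genes_in_cluster(fit$stats, cl)
    g[order(r[g])][seq_len(min(top_n, length(g)))]
  })))
  if (length(genes) == 0L)
    return(data.frame(cluster = character(0), gene = character(0),
                      DR = numeric(0), MDGE = numeric(0)))
  rows <- lapply(names(fit$stats), function(cl)
    data.frame(cluster = cl, gene = genes,
               DR = fit$stats[[cl]][genes, "DR"],
               MDGE = fit$stats[[cl]][genes, "MDGE"],
               row.names = NULL, stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

plot_dotplot <- function(dp, id, n_markers) {
  if (nrow(dp) == 0L || length(unique(dp$gene)) == 0L) {
    plot_empty(sprintf("%s: 0 marker genes", id))
    return(invisible())
  }
  gx <- factor(dp$gene, levels = unique(dp$gene))
  cy <- factor(dp$cluster)
  shade <- if (max(dp$MDGE) > 0) 1 - 0.8 * dp$MDGE / max(dp$MDGE)
           else rep(0.5, nrow(dp))
  graphics::plot(as.integer(gx), as.integer(cy), cex = 3 * sqrt(dp$DR),
                 pch = 16, col = grDevices::grey(shade),
                 xaxt = "n", yaxt = "n",
                 xlab = "", ylab = "cluster",
                 main = sprintf("%s: top marker genes (%d total)",
                                id, n_markers))
  graphics::axis(1, at = seq_along(levels(gx)), labels = levels(gx),
                 las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_along(levels(cy)), labels = levels(cy),
                 las = 1)
}
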