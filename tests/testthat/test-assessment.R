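test_that("count_significant_genes counts by FDR and direction", {
  tab <- fake_pair_table(logGER = c(2, 1, -1), FDR = c(.01, .01, .01))
  expect_equal(count_significant_genes(tab, 0.05, "both"), 3)
  expect_equal(count_significant_genes(tab, 0.05, "positive", "A"), 2)
  expect_equal(count_significant_genes(tab, 0.05, "positive", "B"), 1)
  # empty tested set and all-FDR-1 both give zero
  empty <- fake_pair_table(numeric(0), numeric(0))
  expect_equal(count_significant_genes(empty, 0.05, "both"), 0)
  ones <- fake_pair_table(c(1, 2), c(1, 1))
  expect_equal(count_significant_genes(ones, 0.05, "both"), 0)
  expect_error(count_significant_genes(tab, 0.05, "positive", "Z"),
               "pair")
})

make_combn <- function(counts, clusters) {
  # counts: named vector like c("A-B" = 5, ...) of significant genes
  out <- lapply(names(counts), function(key) {
    pr <- strsplit(key, "-")[[1]]
    n <- counts[[key]]
    fake_pair_table(logGER = rep(1, max(n, 1)),
                    FDR = c(rep(0.01, n), rep(1, max(1 - n, 0)))[
                      seq_len(max(n, 1))],
                    pair = pr)
  })
  names(out) <- names(counts)
  structure(out, class = "de_combn", solution_id = "fake")
}

test_that("nearest neighbour is the argmin of significant-gene counts", {
  combn3 <- make_combn(c("A-B" = 5, "A-C" = 0, "B-C" = 2),
                       c("A", "B", "C"))
  nb <- find_nearest_neighbors(combn3)
  expect_equal(nb, c(A = "C", B = "C", C = "A"))
  # two clusters: each is the other's neighbour
  combn2 <- make_combn(c("A-B" = 4), c("A", "B"))
  expect_equal(find_nearest_neighbors(combn2), c(A = "B", B = "A"))
  # tie broken by cluster-name order
  tie <- make_combn(c("A-B" = 2, "A-C" = 2, "B-C" = 9),
                    c("A", "B", "C"))
  expect_equal(find_nearest_neighbors(tie)[["A"]], "B")
})

test_that("de_neighb finds the constructed separating gene", {
  # two clusters differing in exactly one strongly elevated gene
  set.seed(21)
  n <- 60
  x <- matrix(rpois(20 * 2 * n, 1), 20, 2 * n)
  x[1, seq_len(n)] <- rpois(n, 12)      # g1 high in cluster A
  m <- toy_matrix(x)
  s <- cluster_solution(rep(c("A", "B"), each = n), colnames(m$values))
  fit <- calc_scv(m, s)
  nb <- de_neighb(fit, 0.05)
  expect_true("g1" %in% nb$A)
  expect_false("g1" %in% nb$B)
  # all-FDR-1 pair yields empty sets
  ones <- make_combn(c("A-B" = 0), c("A", "B"))
  expect_equal(lengths(de_neighb(ones, 0.05)), c(A = 0L, B = 0L))
})

test_that("markers require positivity against every other cluster", {
  # g1 positive for A vs both B and C; g2 positive vs B only
  tabAB <- fake_pair_table(c(2, 2), c(.01, .01), c("A", "B"),
                           c("g1", "g2"))
  tabAC <- fake_pair_table(c(2, -2), c(.01, .01), c("A", "C"),
                           c("g1", "g2"))
  tabBC <- fake_pair_table(c(0, 0), c(1, 1), c("B", "C"),
                           c("g1", "g2"))
  combn <- structure(list("A-B" = tabAB, "A-C" = tabAC, "B-C" = tabBC),
                     class = "de_combn", solution_id = "fake")
  mk <- de_marker(combn, 0.05)
  expect_equal(mk$A, "g1")
  expect_length(mk$B, 0)
  expect_length(mk$C, 0)
})

test_that("marker sets are subsets of neighbour-DE sets", {
  for (seed in 1:4) {
    fx <- random_fixture(60, 60, 3, seed + 100)
    fit <- calc_scv(fx$m, fx$s)
    mk <- de_marker(fit)
    nb <- de_neighb(fit)
    for (cl in names(mk))
      expect_true(all(mk[[cl]] %in% nb[[cl]]))
  }
  # and for a 2-cluster solution the two sets coincide
  fx <- random_fixture(60, 50, 2, 300)
  fit <- calc_scv(fx$m, fx$s)
  expect_equal(de_marker(fit), de_neighb(fit))
})

test_that("silhouette widths match the hand formula on a line", {
  emb <- matrix(c(0, 1, 10, 11), 4, 1,
                dimnames = list(c("c1", "c2", "c3", "c4"), "d1"))
  s <- cluster_solution(c("A", "A", "B", "B"), rownames(emb))
  sw <- silhouette_widths(emb, s)
  expect_equal(sw$cell$width[1], 9.5 / 10.5, tolerance = 1e-12)
  expect_true(all(sw$cell$width >= -1 & sw$cell$width <= 1))
})

test_that("degenerate silhouette cases use the 0 convention", {
  emb <- matrix(0, 4, 2, dimnames = list(sprintf("c%d", 1:4), NULL))
  s <- cluster_solution(c("A", "A", "B", "B"), rownames(emb))
  expect_equal(silhouette_widths(emb, s)$cell$width, rep(0, 4))
  # singleton cluster gets width 0 for its cell
  emb2 <- matrix(c(0, 1, 5, 2, 2, 2), 3, 2,
                 dimnames = list(sprintf("c%d", 1:3), NULL))
  s2 <- cluster_solution(c("A", "A", "B"), rownames(emb2))
  expect_equal(silhouette_widths(emb2, s2)$cell$width[3], 0)
})

test_that("silhouette agrees with the brute-force oracle", {
  set.seed(31)
  for (i in 1:15) {
    n <- sample(10:60, 1)
    d <- sample(1:10, 1)
    k <- sample(2:5, 1)
    emb <- matrix(rnorm(n * d), n, d,
                  dimnames = list(sprintf("c%d", 1:n), NULL))
    lab <- sample(sprintf("cl%d", 1:k), n, replace = TRUE)
    lab[1:k] <- sprintf("cl%d", 1:k)
    s <- cluster_solution(lab, rownames(emb))
    sw <- silhouette_widths(emb, s)
    expect_equal(sw$cell$width, silhouette_oracle(emb, lab),
                 tolerance = 1e-9)
  }
})

test_that("silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(32)
  emb <- matrix(rnorm(80), 40, 2,
                dimnames = list(sprintf("c%d", 1:40), NULL))
  lab <- rep(c("x", "y", "z", "w"), 10)
  s <- cluster_solution(lab, rownames(emb))
  sw <- silhouette_widths(emb, s)
  ref <- cluster::silhouette(as.integer(factor(lab)), dist(emb))
  expect_equal(sw$cell$width, as.numeric(ref[, "sil_width"]),
               tolerance = 1e-9)
})

test_that("silhouette input mismatches are errors", {
  emb <- matrix(0, 3, 2, dimnames = list(sprintf("c%d", 1:3), NULL))
  s <- cluster_solution(c("A", "B"), c("c1", "c9"))
  expect_error(silhouette_widths(emb, s), "match")
})

test_that("summarize_resolution tallies a constructed 3-cluster fixture", {
  sim <- simulate_dataset(simulation_spec(n_clusters = 3,
    cells_per_cluster = 30, n_genes = 120, de_genes_per_cluster = 8,
    seed = 5))
  fit <- calc_scv(sim$matrix, cluster_solution(sim$labels,
                                               solution_id = "k3"),
                  sim$embedding)
  sm <- summarize_resolution(fit)
  expect_equal(sm$n_clusters, 3)
  expect_equal(sm$neighb_counts, lengths(de_neighb(fit)))
  expect_equal(sm$marker_counts, lengths(de_marker(fit)))
  expect_equal(sm$passed, all(sm$neighb_counts >= 1))
  # the flag flips when any count is zero
  expect_false(all(c(sm$neighb_counts, 0) >= 1))
})

test_that("sweep orders by cluster count and stops on loss", {
  sim <- simulate_dataset(simulation_spec(seed = 6))
  series <- build_resolution_series(sim$labels, sim$matrix,
                                    ks = c(3, 5, 6), seed = 6)
  # scramble the input order; sweep must sort by cluster count
  sw <- sweep_resolutions(sim$matrix, series[c(2, 3, 1)],
                          stop_on_loss = FALSE)
  expect_equal(sw$summary$n_clusters, c(3, 5, 6))
  sw2 <- sweep_resolutions(sim$matrix, series, stop_on_loss = FALSE)
  expect_equal(sw$summary, sw2$summary)

  # stop_on_loss: failing solution is retained, later ones are not run
  stopped <- sweep_resolutions(sim$matrix, series, stop_on_loss = TRUE)
  if (any(stopped$summary$passed %in% FALSE)) {
    last <- nrow(stopped$summary)
    expect_false(stopped$summary$passed[last])
    expect_true(all(stopped$summary$passed[-last] %in% c(TRUE, NA)))
  }
})

test_that("sweep handles single-cluster and single-solution input", {
  fx <- random_fixture(20, 15, 1, 12)
  sw <- sweep_resolutions(fx$m, list(fx$s), stop_on_loss = TRUE)
  expect_equal(nrow(sw$summary), 1L)
  expect_true(is.na(sw$summary$passed))
  expect_null(sw$scvs[[1]]$de_combn)
})

test_that("scv summary prints per-cluster counts", {
  sim <- simulate_dataset(simulation_spec(n_clusters = 2,
    cells_per_cluster = 20, n_genes = 60, de_genes_per_cluster = 5,
    seed = 7))
  fit <- calc_scv(sim$matrix, cluster_solution(sim$labels),
                  sim$embedding)
  sm <- summary(fit)
  expect_s3_class(sm, "summary.scv")
  expect_equal(nrow(sm$table), 2)
  expect_output(print(sm), "passed neighbour check")
})

test_that("external DE results can replace the built-in tables", {
  fx <- random_fixture(30, 40, 2, 400)
  fit <- calc_scv(fx$m, fx$s)
  # an externally produced pairwise table: same schema, made-up values
  genes <- rownames(fit$stats[[1]])
  ext <- data.frame(logGER = rep(1, length(genes)),
                    dDR = rep(0.2, length(genes)),
                    p_value = rep(0.001, length(genes)),
                    FDR = rep(0.004, length(genes)),
                    tested = TRUE, row.names = genes)
  fit2 <- set_de_results(fit, de_combn = list("cl1-cl2" = ext))
  expect_equal(lengths(de_marker(fit2)),
               c(cl1 = length(genes), cl2 = 0L))
  # schema violations are rejected without recomputation
  expect_error(set_de_results(fit, de_combn = list("cl1-cl2" =
    ext[, setdiff(colnames(ext), "FDR")])), "lacks column")
  expect_error(set_de_results(fit, de_combn = list("bad-key" = ext)),
               "pair keys")
  bad <- ext; bad$p_value <- 2
  expect_error(set_de_results(fit, de_combn = list("cl1-cl2" = bad)),
               "invalid p-values")
  bad2 <- ext[-1, ]
  expect_error(set_de_results(fit, de_combn = list("cl1-cl2" = bad2)),
               "gene universe")
  # vs-rest replacement follows the same contract
  vs <- ext[, c("logGER", "p_value", "FDR", "tested")]
  fit3 <- set_de_results(fit, de_vs_rest = list(cl1 = vs, cl2 = vs))
  expect_equal(fit3$de_vs_rest$cl1, vs)
  expect_error(set_de_results(fit, de_vs_rest = list(cl1 = vs)),
               "exactly the clusters")
})
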