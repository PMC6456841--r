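# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately use brute force / direct formulas, never the
# package's own code paths.

# exact two-sided Wilcoxon rank-sum p by exhaustive enumeration of all
# C(nA+nB, nA) assignments of the pooled ranks (tie-free data only)
enumerate_wilcox_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  splits <- utils::combn(na + nb, na)
  ranks <- seq_len(na + nb)
  w_all <- apply(splits, 2, function(idx) sum(ranks[idx])) -
    na * (na + 1) / 2
  mu <- na * nb / 2
  # two-sided: as extreme or more, symmetric around the mean
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

# textbook BH step-up, written independently of stats::p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force silhouette widths straight from the definition
silhouette_oracle <- function(embedding, labels) {
  n <- nrow(embedding)
  d <- as.matrix(dist(embedding))
  vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1L) return(0)
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    m <- max(a, b)
    if (m == 0) 0 else (b - a) / m
  }, numeric(1))
}

# tiny deterministic expression fixture: explicit de-logged values packed
# into a norm_matrix (log2, pseudocount 1)
toy_matrix <- function(delogged, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(delogged)))
  if (is.null(cells)) cells <- sprintf("c%d", seq_len(ncol(delogged)))
  m <- log2(delogged + 1)
  dimnames(m) <- list(genes, cells)
  norm_matrix(m, log_base = 2, norm_pseudocount = 1)
}

# random de-logged fixture with a given cluster labelling
random_fixture <- function(n_genes, n_cells, k, seed) {
  set.seed(seed)
  x <- matrix(rpois(n_genes * n_cells, lambda = 0.8), n_genes, n_cells)
  m <- toy_matrix(x)
  labels <- sample(sprintf("cl%d", seq_len(k)), n_cells, replace = TRUE)
  # guarantee every cluster is populated
  labels[seq_len(k)] <- sprintf("cl%d", seq_len(k))
  s <- cluster_solution(labels, colnames(m$values), "rnd")
  list(m = m, s = s)
}

# a deterministic pairwise table with a pair attribute, for unit tests
fake_pair_table <- function(logGER, FDR, pair = c("A", "B"),
                            genes = sprintf("g%d", seq_along(logGER))) {
  tab <- data.frame(logGER = logGER, dDR = rep(0, length(logGER)),
                    p_value = FDR, FDR = FDR,
                    tested = !is.na(FDR), row.names = genes)
  attr(tab, "pair") <- pair
  tab
}
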