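test_that("pairwise gene filter keeps genes detected in either cluster", {
  dr_a <- c(g1 = 0.15, g2 = 0.05, g3 = 0.00)
  dr_b <- c(g1 = 0.05, g2 = 0.05, g3 = 0.80)
  expect_setequal(filter_genes_pairwise(dr_a, dr_b, 0.10),
                  c("g1", "g3"))
  expect_length(filter_genes_pairwise(dr_a, dr_b, 0.5), 1L)
  # threshold 0 is vacuous
  expect_setequal(filter_genes_pairwise(dr_a, dr_b, 0),
                  c("g1", "g2", "g3"))
})

test_that("wilcoxon_pvalue handles canonical small cases", {
  expect_equal(wilcoxon_pvalue(c(1, 2, 3), c(1, 2, 3)), 1.0)
  # complete separation of 3 vs 3: 2 of the 20 rank splits are as extreme
  expect_equal(wilcoxon_pvalue(c(5, 6, 7), c(1, 2, 3)), 0.1)
  expect_equal(wilcoxon_pvalue(c(1, 2, 3), c(5, 6, 7)), 0.1)
  expect_error(wilcoxon_pvalue(1, numeric(0)), "non-empty")
})

test_that("exact p matches exhaustive enumeration for all small splits", {
  set.seed(42)
  for (n in 2:12) {
    for (na in 1:(n - 1)) {
      vals <- sample(seq_len(100), n)    # tie-free
      a <- vals[seq_len(na)]
      b <- vals[(na + 1):n]
      expect_equal(wilcoxon_pvalue(a, b), enumerate_wilcox_p(a, b),
                   info = sprintf("nA=%d nB=%d", na, n - na))
    }
  }
})

test_that("p-values agree with the conventional base-R test", {
  set.seed(43)
  # exact regime
  for (i in 1:20) {
    a <- sample(1000, sample(3:20, 1))
    b <- sample(2000, sample(3:20, 1)) + 0.5
    expect_equal(wilcoxon_pvalue(a, b), wilcox.test(a, b)$p.value)
  }
  # tied / large-sample regime (tie-corrected normal approximation)
  for (i in 1:20) {
    a <- rpois(30, 1)
    b <- rpois(40, 2)
    expect_equal(wilcoxon_pvalue(a, b),
                 suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE)$p.value))
  }
  for (i in 1:5) {
    a <- rnorm(40); b <- rnorm(35)
    expect_equal(wilcoxon_pvalue(a, b),
                 wilcox.test(a, b, exact = FALSE,
                             correct = TRUE)$p.value)
  }
})

test_that("wilcoxon_pvalue is symmetric and monotone-invariant", {
  set.seed(44)
  for (i in 1:10) {
    a <- rpois(15, 2); b <- rpois(12, 3)
    expect_equal(wilcoxon_pvalue(a, b), wilcoxon_pvalue(b, a))
    expect_equal(wilcoxon_pvalue(a, b),
                 wilcoxon_pvalue(2^a - 1, 2^b - 1))
  }
})

test_that("bh_adjust reproduces the step-up computation", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(45)
  for (i in 1:50) {
    p <- runif(sample(1:100, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("adjusted values never fall below their p-values", {
  set.seed(46)
  p <- runif(200)^2
  expect_true(all(bh_adjust(p) >= p))
})

test_that("calc_logGER follows the closed form and its symmetries", {
  expect_equal(calc_logGER(2, 2, 1), 0)
  expect_equal(calc_logGER(2, 2, 1e-9), 0)
  expect_equal(calc_logGER(3, 1, 1e-12), log2(3), tolerance = 1e-3)
  # vanishing pseudocount sends zero comparisons past magnitude 300
  expect_gt(abs(calc_logGER(1, 0, 1e-99)), 300)
  # antisymmetry
  expect_equal(calc_logGER(5, 2, 0.01), -calc_logGER(2, 5, 0.01))
  expect_error(calc_logGER(1, 1, 0), "positive")
  expect_error(calc_logGER(-1, 1, 1), "non-negative")
})

test_that("calc_logGER is monotone in each mean", {
  pc <- 1 / 200
  a <- seq(0, 10, by = 0.5)
  expect_true(all(diff(calc_logGER(a, 3, pc)) > 0))
  expect_true(all(diff(calc_logGER(3, a, pc)) < 0))
})

test_that("a pseudocount of 1 always compresses the true ratio", {
  set.seed(47)
  a <- runif(500, 0.01, 50)
  b <- runif(500, 0.01, 50)
  expect_true(all(abs(calc_logGER(a, b, 1)) <= abs(log2(a / b)) + 1e-12))
})

test_that("calc_dDR is a bounded antisymmetric difference", {
  expect_equal(calc_dDR(0.8, 0.3), 0.5)
  expect_equal(calc_dDR(0.4, 0.4), 0)
  expect_equal(calc_dDR(0, 1), -1)
  expect_error(calc_dDR(1.2, 0), "\\[0, 1\\]")
})

test_that("vs-rest equals the pairwise view for a 2-cluster solution", {
  fx <- random_fixture(50, 40, 2, 8)
  vs <- calc_de_vs_rest(fx$m, fx$s)
  pw <- calc_de_combn(fx$m, fx$s)
  key <- names(pw)[1]
  pair <- attr(pw[[key]], "pair")
  # with two clusters, "rest" of one IS the other
  expect_equal(vs[[pair[1]]]$p_value, pw[[key]]$p_value)
  expect_equal(vs[[pair[1]]]$logGER, pw[[key]]$logGER)
  expect_equal(vs[[pair[2]]]$logGER, -pw[[key]]$logGER)
  expect_equal(vs[[pair[1]]]$tested, pw[[key]]$tested)
})

test_that("untested genes keep logGER but carry no p/FDR", {
  # g2 undetected everywhere: below any positive DR threshold
  x <- rbind(g1 = c(5, 6, 7, 0, 1, 0), g2 = rep(0, 6))
  m <- toy_matrix(x)
  s <- cluster_solution(rep(c("A", "B"), each = 3), colnames(m$values))
  vs <- calc_de_vs_rest(m, s)
  expect_false(vs$A["g2", "tested"])
  expect_true(is.na(vs$A["g2", "p_value"]) && is.na(vs$A["g2", "FDR"]))
  expect_true(is.finite(vs$A["g2", "logGER"]))
  expect_true(vs$A["g1", "tested"])
})

test_that("FDR is adjusted within each comparison's tested set", {
  fx <- random_fixture(60, 50, 3, 9)
  pw <- calc_de_combn(fx$m, fx$s)
  for (tab in pw) {
    tested <- tab$tested
    expect_equal(tab$FDR[tested], bh_oracle(tab$p_value[tested]))
    expect_true(all(is.na(tab$FDR[!tested])))
  }
})

test_that("calc_de_combn produces one oriented table per unordered pair", {
  fx <- random_fixture(30, 60, 4, 10)
  pw <- calc_de_combn(fx$m, fx$s)
  expect_length(pw, choose(4, 2))
  expect_setequal(names(pw),
                  combn(levels(fx$s$labels), 2, paste, collapse = "-"))
  # orientation: recompute with swapped stats must flip both effects
  st <- compute_cluster_gene_stats(fx$m, fx$s)
  tab <- pw[[1]]
  pair <- attr(tab, "pair")
  pc <- 1 / ncol(fx$m$values)
  expect_equal(tab$logGER,
               calc_logGER(st[[pair[1]]]$MGE, st[[pair[2]]]$MGE, pc))
  expect_equal(tab$dDR, st[[pair[1]]]$DR - st[[pair[2]]]$DR)
  expect_true(all(abs(tab$dDR) <= 1))
})

test_that("single-cluster solutions cannot be tested", {
  fx <- random_fixture(10, 10, 1, 11)
  expect_error(calc_de_vs_rest(fx$m, fx$s), "at least two")
  expect_error(calc_de_combn(fx$m, fx$s), "at least two")
})

test_that("cluster names containing the pair separator are rejected", {
  m <- toy_matrix(matrix(rpois(40, 1), 4, 10))
  s <- cluster_solution(rep(c("a-1", "b"), 5), colnames(m$values))
  expect_error(calc_de_combn(m, s), "may not contain")
})

test_that("a 4-fold elevated gene reaches FDR < 0.05 vs rest", {
  sim <- simulate_dataset(simulation_spec(seed = 3))
  s <- cluster_solution(sim$labels, solution_id = "true")
  vs <- calc_de_vs_rest(sim$matrix, s)
  for (cl in names(vs)) {
    hits <- sim$de_genes[[cl]]
    fdr <- vs[[cl]][hits, "FDR"]
    expect_true(mean(fdr < 0.05, na.rm = TRUE) >= 0.8,
                info = paste("cluster", cl))
  }
})
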