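test_that("vectorized rank-sum test matches wilcox.test in both regimes", {
  set.seed(1)
  # exact branch: small groups, no ties
  m_small <- matrix(rnorm(40 * 6), 40, 6,
                    dimnames = list(NULL, sprintf("g%d", 1:6)))
  g1 <- rep(c(TRUE, FALSE), each = 20)
  p_pkg <- mgpop:::rank_sum_pvalues(m_small, g1)
  p_ref <- apply(m_small, 2, function(v) {
    wilcox.test(v[g1], v[!g1], exact = TRUE)$p.value
  })
  expect_equal(unname(p_pkg), unname(p_ref), tolerance = 1e-12)

  # approximate branch with ties (counts)
  m_ties <- matrix(rpois(120 * 6, 2), 120, 6,
                   dimnames = list(NULL, sprintf("g%d", 1:6)))
  g2 <- rep(c(TRUE, FALSE), each = 60)
  p_pkg2 <- mgpop:::rank_sum_pvalues(m_ties, g2)
  p_ref2 <- apply(m_ties, 2, function(v) {
    suppressWarnings(wilcox.test(v[g2], v[!g2], exact = FALSE,
                                 correct = TRUE)$p.value)
  })
  expect_equal(unname(p_pkg2), unname(p_ref2), tolerance = 1e-10)

  # all values tied is untestable
  expect_true(is.na(mgpop:::rank_sum_pvalues(
    matrix(1, 10, 1, dimnames = list(NULL, "g")), rep(c(TRUE, FALSE), 5))))
})

test_that("pairwise DE detects planted markers with correct direction", {
  set.seed(2)
  n <- 200
  counts <- matrix(rnbinom(n * 50, mu = 5, size = 2), n, 50)
  counts[1:100, 1] <- rnbinom(100, mu = 20, size = 2)   # up in cluster 1
  dimnames(counts) <- list(sprintf("c%d", 1:n), sprintf("g%d", 1:50))
  labels <- rep(1:2, each = 100)
  de <- pairwise_de(counts, labels)
  hit <- de[de$gene == "g1", ]
  expect_lt(hit$p_adj, 0.01)
  expect_equal(hit$direction, 1)
  expect_true(all(de$p_adj >= de$p))

  # genes undetected in both groups are excluded from the pair universe
  counts2 <- counts
  counts2[, 2] <- 0
  de2 <- pairwise_de(counts2, labels)
  expect_false("g2" %in% de2$gene)

  expect_error(pairwise_de(counts, rep(1, n)), ">= 2 clusters")
  expect_error(pairwise_de(counts[1:3, ], c(1, 1, 2)), ">= 2 cells")
})

test_that("label permutation keeps the raw type-I rate near nominal", {
  set.seed(3)
  counts <- matrix(rnbinom(300 * 400, mu = 4, size = 2), 300, 400,
                   dimnames = list(sprintf("c%d", 1:300),
                                   sprintf("g%d", 1:400)))
  labels <- sample(rep(1:2, each = 150))
  de <- pairwise_de(counts, labels)
  frac <- mean(de$p < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.08)
})

test_that("gene ranking honors the never-downregulated constraint", {
  # constructed 3-cluster outcome via an injected deterministic test:
  # gene A up in cl1 vs both others; gene B up vs cl2 but down vs cl3;
  # gene C up vs cl3 only.
  counts <- matrix(5, 30, 4, dimnames = list(
    sprintf("c%d", 1:30), c("A", "B", "C", "D")))
  labels <- rep(1:3, each = 10)
  # means control the recorded direction; the injected test sets p-values
  counts[labels == 1, "A"] <- 50
  counts[labels == 1, "B"] <- 50
  counts[labels == 3, "B"] <- 100
  counts[labels %in% c(1, 2), "C"] <- 50
  # filler keeps per-cell totals constant so CPM direction = count direction
  counts[, "D"] <- 200 - rowSums(counts[, c("A", "B", "C")])
  fake_test <- function(m, in_a) {
    setNames(rep(1e-6, ncol(m)), colnames(m))
  }
  de <- pairwise_de(counts, labels, test = fake_test)
  ranked <- rank_cluster_genes(de, cluster = 1)
  expect_equal(ranked$gene[1], "A")           # up-count 2, never down
  expect_equal(ranked$up_count[ranked$gene == "A"], 2L)
  expect_false("B" %in% ranked$gene)          # down vs cluster 3: excluded
  expect_true("C" %in% ranked$gene)           # equal vs 2, up vs 3 only
  expect_equal(ranked$up_count[ranked$gene == "C"], 1L)
})

test_that("top-N signatures truncate, warn and stay deterministic", {
  ranked <- tibble::tibble(gene = sprintf("g%d", 1:30),
                           up_count = 30:1, best_p_adj = 1e-4,
                           rank = 1:30)
  expect_warning(top <- signature_top_n(ranked, 50), "only 30")
  expect_length(top, 30)
  expect_identical(signature_top_n(ranked, 5), sprintf("g%d", 1:5))
  expect_length(signature_top_n(ranked, 0), 0)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  set.seed(4)
  for (m in c(1, 3, 5, 10)) {
    p <- runif(m)
    expect_equal(p.adjust(p, "BH"), bh_bruteforce(p), tolerance = 1e-12)
  }
  # with heavy ties
  p <- c(0.01, 0.01, 0.5, 0.5, 0.9)
  expect_equal(p.adjust(p, "BH"), bh_bruteforce(p), tolerance = 1e-12)
})

test_that("dot-plot statistics match an element-wise oracle", {
  set.seed(5)
  counts <- tiny_counts(matrix(rpois(60 * 5, 2), 60, 5))
  counts[, 1] <- counts[, 1] + 1                # no zero-total cells
  counts[, 4] <- 0                              # gene absent everywhere
  counts[1:30, 5] <- pmax(counts[1:30, 5], 1)   # detected in cluster 1 only
  counts[31:60, 5] <- 0
  expr <- normalize_cpm_log(counts)
  labels <- rep(1:2, each = 30)
  stats <- dotplot_stats(expr, labels, colnames(counts))

  absent <- stats[stats$gene == "g4", ]
  expect_true(all(absent$frac_detected == 0))
  expect_true(all(absent$mean_z == 0))

  marker <- stats[stats$gene == "g5", ]
  expect_equal(marker$frac_detected[marker$cluster == 1], 1)
  expect_equal(marker$frac_detected[marker$cluster == 2], 0)

  z <- zscore_genes(expr)
  for (cl in 1:2) {
    expect_equal(
      stats$mean_z[stats$gene == "g1" & stats$cluster == cl],
      mean(z[labels == cl, "g1"]),
      tolerance = 1e-12
    )
  }
})

test_that("signatures exclude genes downregulated anywhere (hard assertion)", {
  ref <- simulate_reference(sim_config(n_cells = 400, n_genes = 200,
                                       n_clusters = 3,
                                       n_markers_per_cluster = 10,
                                       satellite_clusters = 2, seed = 13))
  labels <- ref$truth$clusters$cluster
  de <- pairwise_de(ref$counts, labels)
  sig <- cluster_signatures(de, top_n = 20)
  alpha <- attr(de, "alpha")
  for (cl in 1:3) {
    o <- mgpop:::orient_de(de, cl)
    down <- unique(o$gene[o$p_adj < alpha & o$direction < 0])
    expect_length(intersect(sig$full[[paste0("cluster_", cl)]], down), 0)
  }
})
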