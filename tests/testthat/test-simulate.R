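small_cfg <- function(...) {
  sim_config(n_cells = 300, n_genes = 200, n_clusters = 3,
             n_markers_per_cluster = 10, satellite_clusters = 2,
             n_donors = 4, seed = 11, ...)
}

test_that("reference simulation is deterministic given the seed", {
  a <- simulate_reference(small_cfg())
  b <- simulate_reference(small_cfg())
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$clusters, b$truth$clusters)
})

test_that("simulation config invariants are enforced", {
  expect_error(sim_config(n_clusters = 3,
                          cluster_proportions = c(0.5, 0.4, 0.2)),
               "sum")
  expect_error(sim_config(n_genes = 20, n_clusters = 5,
                          n_markers_per_cluster = 10),
               "exceeds n_genes")
  expect_error(sim_config(core_cluster_index = 2,
                          satellite_clusters = c(2, 3)))
  truth <- simulate_reference(small_cfg())$truth
  expect_equal(anyDuplicated(unlist(truth$markers)), 0)  # disjoint markers
  expect_equal(nrow(truth$clusters), 300)
})

test_that("marker fold change matches the stated generator model", {
  # markers x 2^2 in their own cluster: empirical own/rest mean count ratio
  # should be about 4 (Monte-Carlo, no satellites or batch effects)
  cfg <- sim_config(n_cells = 2000, n_genes = 300, n_clusters = 3,
                    n_markers_per_cluster = 10, marker_log2fc = 2,
                    batch_scale = 0, satellite_clusters = integer(0),
                    satellite_weight = 0, seed = 2)
  ref <- simulate_reference(cfg)
  counts <- as.matrix(ref$counts)
  cl <- ref$truth$clusters$cluster
  ratios <- unlist(lapply(1:3, function(k) {
    mk <- ref$truth$markers[[k]]
    own <- colMeans(counts[cl == k, mk, drop = FALSE])
    rest <- colMeans(counts[cl != k, mk, drop = FALSE])
    own / rest
  }))
  expect_lt(abs(mean(ratios) - 4), 0.4)  # within 10 percent
})

test_that("null generator produces exchangeable clusters", {
  cfg <- sim_config(n_cells = 600, n_genes = 150, n_clusters = 2,
                    n_markers_per_cluster = 5, marker_log2fc = 0,
                    batch_scale = 0, satellite_clusters = integer(0),
                    satellite_weight = 0, seed = 8)
  ref <- simulate_reference(cfg)
  counts <- as.matrix(ref$counts)
  cl <- ref$truth$clusters$cluster
  p <- apply(counts, 2, function(v) {
    if (var(v) == 0) return(NA_real_)
    suppressWarnings(wilcox.test(v[cl == 1], v[cl == 2])$p.value)
  })
  frac <- mean(p < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.10)
})

test_that("generated library sizes bracket the QC window", {
  ref <- simulate_reference(sim_config(n_cells = 3000, n_genes = 300,
                                       seed = 4))
  totals <- Matrix::rowSums(ref$counts)
  expect_gt(sum(totals <= 1000), 0)
  expect_gt(sum(totals > 1000 & totals < 10000), 2500)
})

test_that("query depletion follows the closed-form renormalization", {
  # depleting a 20 percent cluster by half: case-group expected proportion
  # 0.2 * 0.5 / (1 - 0.1) = 1/9
  cfg <- sim_config(n_cells = 100, n_genes = 60, n_clusters = 5,
                    n_markers_per_cluster = 5, seed = 3,
                    satellite_clusters = integer(0), satellite_weight = 0)
  ref <- simulate_reference(cfg)
  q <- simulate_query(ref$truth, n_cells = 20000, depleted_cluster = 2,
                      depletion_fraction = 0.5, n_donors = 10, seed = 9)
  cl <- q$truth$clusters$cluster
  grp <- q$meta$group
  p_case <- mean(cl[grp == "case"] == 2)
  p_ctrl <- mean(cl[grp == "control"] == 2)
  expect_lt(abs(p_case - 1 / 9), 0.012)
  expect_lt(abs(p_ctrl - 0.2), 0.012)
  expect_error(simulate_query(ref$truth, depleted_cluster = 99), "unknown")
})

test_that("query with no depletion matches reference proportions", {
  cfg <- small_cfg()
  ref <- simulate_reference(cfg)
  q <- simulate_query(ref$truth, n_cells = 12000, depleted_cluster = 1,
                      depletion_fraction = 0, n_donors = 8, seed = 5)
  props <- prop.table(table(q$truth$clusters$cluster))
  expect_true(all(abs(props - 1 / 3) < 0.03))
})

test_that("intensity generator matches its Gaussian tail and planted high rate", {
  # pure Gaussian: about 2.28 percent above mean + 2 SD
  tbl <- simulate_intensity_table(n_cells = 1e5, high_fraction = 0,
                                  base_positive_frac = 1, seed = 6)
  thr <- high_expressor_threshold(tbl$intensity, 2)
  expect_lt(abs(mean(tbl$intensity > thr) - 0.0228), 0.004)

  # planted 5 percent at +4 SD recovered within one percentage point
  tbl2 <- simulate_intensity_table(n_cells = 1e4, high_fraction = 0.05,
                                   high_offset_sd = 4,
                                   base_positive_frac = 1, seed = 7)
  thr2 <- high_expressor_threshold(tbl2$intensity, 2)
  expect_lt(abs(100 * mean(tbl2$intensity > thr2) - 5), 1)

  # degenerate: constant intensities give zero high cells
  const <- rep(7, 100)
  expect_equal(sum(const > high_expressor_threshold(const)), 0)
})

test_that("trait list generator plants and randomizes as designed", {
  truth <- simulate_reference(small_cfg())$truth
  tr <- simulate_trait_lists(truth, n_traits = 3, design = "planted",
                             planted_cluster = 2, planted_sign = -1,
                             genes_per_list = 10, seed = 4)
  planted <- tr$gene[tr$trait == "trait_01" & tr$sign == -1]
  expect_true(all(planted %in% truth$markers[[2]]))
  expect_equal(sort(unique(tr$sign)), c(-1, 1))
  expect_error(simulate_trait_lists(truth, n_traits = 0), "empty")
})
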