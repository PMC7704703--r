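test_that("adjusted Rand index handles the canonical special cases", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(rep(1, 6), 1:6), 0)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               ari_bruteforce(c(1, 1, 2, 2), c(1, 2, 1, 2)))
})

test_that("ARI equals the pair-counting oracle and external reference", {
  set.seed(7)
  for (i in 1:20) {
    a <- sample(1:4, 12, replace = TRUE)
    b <- sample(1:3, 12, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_bruteforce(a, b),
                 tolerance = 1e-12)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("single clustering pass recovers well-separated blobs", {
  blobs <- make_pair(n_per = 200, sep = 10, d = 10, seed = 1)
  for (n_pcs in c(5, 8)) {
    for (res in c(0.2, 0.8)) {
      lab <- cluster_once(blobs$x, n_pcs, res, seed = 3)
      expect_equal(adjusted_rand_index(lab, blobs$labels), 1)
    }
  }
  # deterministic given seed
  l1 <- cluster_once(blobs$x, 5, 0.4, seed = 9)
  l2 <- cluster_once(blobs$x, 5, 0.4, seed = 9)
  expect_identical(l1, l2)
  # too many PCs is an error
  expect_error(cluster_once(blobs$x[1:8, ], 10, 0.4), "n_pcs")
})

test_that("robustness assessment separates real from arbitrary splits", {
  blobs <- make_pair(n_per = 120, sep = 10, d = 8, seed = 2)
  pcs <- mgpop:::pca_embed(blobs$x, 5)
  rep_true <- assess_robustness(pcs, blobs$labels, n_iter = 10, seed = 4)
  expect_equal(rep_true$per_cluster$min_accuracy, c(1, 1))

  # one blob's cells split into two arbitrary labels: indistinguishable
  set.seed(5)
  fake <- blobs$labels
  half <- which(fake == 1)
  fake[sample(half, length(half) / 2)] <- 3L
  rep_fake <- assess_robustness(pcs, fake, n_iter = 10, seed = 4)
  acc <- rep_fake$per_cluster
  expect_lt(acc$min_accuracy[acc$cluster == 1], 0.75)
  expect_lt(acc$min_accuracy[acc$cluster == 3], 0.75)

  expect_error(assess_robustness(pcs, rep(1, nrow(pcs))), ">= 2 clusters")
})

test_that("unrobust clusters are merged back into their source", {
  blobs <- make_pair(n_per = 120, sep = 10, d = 8, seed = 3)
  pcs <- mgpop:::pca_embed(blobs$x, 5)
  set.seed(6)
  split_lab <- blobs$labels
  ones <- which(split_lab == 1)
  split_lab[sample(ones, length(ones) / 2)] <- 3L
  out <- merge_unrobust(pcs, split_lab, seed = 7, n_iter = 10)
  expect_equal(length(unique(out$labels)), 2)
  expect_equal(adjusted_rand_index(out$labels, blobs$labels), 1)
  expect_gte(min(out$report$per_cluster$min_accuracy), 0.75)
  expect_gte(nrow(out$history), 1)

  # all clusters already robust: identity
  out2 <- merge_unrobust(pcs, blobs$labels, seed = 7, n_iter = 10)
  expect_identical(out2$labels, as.integer(blobs$labels))
  expect_equal(nrow(out2$history), 0)
})

test_that("merge gate boundary: 0.75 passes, 0.74 merges", {
  blobs <- make_pair(n_per = 20, sep = 10, d = 4, seed = 4)
  pcs <- mgpop:::pca_embed(blobs$x, 3)
  stub <- function(acc2) {
    structure(list(
      per_cluster = tibble::tibble(cluster = 1:2, n_cells = c(20L, 20L),
                                   min_accuracy = c(1, acc2),
                                   mean_accuracy = c(1, acc2)),
      accuracy = NULL,
      confusion = matrix(c(0, 5, 0, 0), 2, 2,
                         dimnames = list(1:2, 1:2)),
      n_iter = 20, train_frac = 0.5
    ), class = "mgpop_robustness")
  }
  keep <- merge_unrobust(pcs, blobs$labels, report = stub(0.75), seed = 1)
  expect_equal(length(unique(keep$labels)), 2)
  merged <- merge_unrobust(pcs, blobs$labels, report = stub(0.74), seed = 1)
  expect_equal(length(unique(merged$labels)), 1)
  expect_equal(merged$history$from, 2L)
})

test_that("grid search recovers three separable blobs at the selected point", {
  centers <- matrix(0, 3, 10)
  centers[2, 1] <- 12
  centers[3, 2] <- 12
  blobs <- make_blobs(n_per = 100, centers = centers, seed = 5)
  cfg <- pipeline_config(pc_grid = 5:7, resolution_grid = c(0.4, 0.8),
                         robustness_iters = 5, seed = 2)
  gs <- grid_search(blobs$x, cfg)
  expect_equal(length(unique(gs$labels)), 3)
  expect_equal(adjusted_rand_index(gs$labels, blobs$labels), 1)
  expect_true(sum(gs$selection$selected) == 1)
  # deterministic given seed
  gs2 <- grid_search(blobs$x, cfg)
  expect_identical(gs$labels, gs2$labels)
})

test_that("iterative subclustering resolves nested structure", {
  # two super-blobs; one contains two sub-blobs -> depth 2, 3 leaves
  centers <- matrix(0, 3, 10)
  centers[1, 1] <- 40                      # distant lone blob
  centers[2, 2] <- 0
  centers[3, 2] <- 8                       # two nearby sub-blobs
  blobs <- make_blobs(n_per = 90, centers = centers, seed = 6)
  cfg <- pipeline_config(pc_grid = c(3, 5), resolution_grid = c(0.2, 0.8),
                         robustness_iters = 5, min_cluster_size = 8,
                         min_de_genes = 1, de_lfc = 1, seed = 3)
  tree <- iterative_subcluster(blobs$x, cfg)
  expect_equal(length(unique(tree$labels$cluster)), 3)
  expect_equal(adjusted_rand_index(tree$labels$cluster, blobs$labels), 1)

  # flat, well-separated blobs: depth 1
  centers2 <- 15 * diag(3)[, c(1, 2, 3)]
  centers2 <- cbind(centers2, matrix(0, 3, 5))
  blobs2 <- make_blobs(n_per = 80, centers = centers2, seed = 7)
  tree2 <- iterative_subcluster(blobs2$x, cfg)
  expect_equal(max(tree2$nodes$depth), 1)
  expect_equal(length(unique(tree2$labels$cluster)), 3)

  # a homogeneous population stays a single leaf
  lone <- make_blobs(n_per = 150, centers = matrix(0, 1, 10), seed = 8)
  tree3 <- iterative_subcluster(lone$x, cfg)
  expect_equal(length(unique(tree3$labels$cluster)), 1)

  # too-small subsets are leaves (stopping rule)
  tiny <- make_blobs(n_per = 7, centers = centers2, seed = 9)
  tree4 <- iterative_subcluster(tiny$x, cfg)
  expect_equal(max(tree4$nodes$depth), 0)
})

test_that("cluster tree tidiers summarise labels and structure", {
  blobs <- make_pair(n_per = 60, sep = 15, d = 6, seed = 10)
  cfg <- pipeline_config(pc_grid = c(3, 4), resolution_grid = 0.4,
                         robustness_iters = 3, min_de_genes = 1, seed = 4)
  tree <- iterative_subcluster(blobs$x, cfg)
  td <- tidy(tree)
  expect_equal(sum(td$n_cells), 120)
  gl <- glance(tree)
  expect_equal(gl$n_cells, 120L)
  expect_equal(gl$n_clusters, length(unique(tree$labels$cluster)))
})

test_that("single-donor reclustering is concordant on shared structure", {
  cfg_sim <- sim_config(n_cells = 800, n_genes = 300, n_clusters = 3,
                        n_markers_per_cluster = 20, marker_log2fc = 3,
                        satellite_clusters = integer(0),
                        satellite_weight = 0, n_donors = 4, seed = 21)
  ref <- simulate_reference(cfg_sim)
  cfg <- pipeline_config(pc_grid = 5:7, resolution_grid = c(0.4, 0.8),
                         robustness_iters = 5, seed = 5)
  prep <- suppressMessages(preprocess(ref$counts, ref$meta, cfg))
  tree <- iterative_subcluster(prep, cfg)
  conc <- suppressWarnings(
    single_donor_concordance(ref$counts, prep$meta, tree$labels, cfg)
  )
  expect_gte(nrow(conc), 2)
  expect_gt(median(conc$ari), 0.5)
})
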