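make_transfer_fixture <- function(seed = 41, shift_scale = 0.1,
                                  depletion = 0, n_query = 600) {
  cfg <- sim_config(n_cells = 600, n_genes = 300, n_clusters = 3,
                    n_markers_per_cluster = 15,
                    satellite_clusters = integer(0), satellite_weight = 0,
                    seed = seed)
  ref <- simulate_reference(cfg)
  q <- simulate_query(ref$truth, n_cells = n_query, depleted_cluster = 2,
                      depletion_fraction = depletion, n_donors = 10,
                      shift_scale = shift_scale, seed = seed + 1)
  ref_expr <- normalize_cpm_log(ref$counts)
  q_expr <- normalize_cpm_log(q$counts)
  shared <- union(select_variable_genes(as.matrix(ref$counts)),
                  select_variable_genes(as.matrix(q$counts)))
  list(ref = ref, q = q, ref_expr = ref_expr, q_expr = q_expr,
       shared = shared)
}

test_that("self-integration yields coinciding embeddings and high correlations", {
  fx <- make_transfer_fixture()
  emb <- cca_integrate(fx$ref_expr, fx$ref_expr, fx$shared, n_cc = 10)
  expect_true(all(abs(emb$canonical_cor) > 0.99))
  agree <- abs(colSums(emb$ref * emb$query) /
                 sqrt(colSums(emb$ref^2) * colSums(emb$query^2)))
  expect_true(all(agree > 0.99))              # coincide up to sign
  expect_false(anyNA(emb$ref))

  # self-transfer identity: reference labels reproduced
  cls <- nb_classify(emb, fx$ref$truth$clusters$cluster)
  expect_gte(mean(cls$assigned_cluster == fx$ref$truth$clusters$cluster),
             0.99)
})

test_that("platform shift does not disturb label transfer", {
  fx <- make_transfer_fixture(seed = 42, shift_scale = 0.15)
  emb <- cca_integrate(fx$ref_expr, fx$q_expr, fx$shared, n_cc = 10)
  cls <- nb_classify(emb, fx$ref$truth$clusters$cluster)
  acc <- mean(cls$assigned_cluster == fx$q$truth$clusters$cluster)
  expect_gte(acc, 0.95)
  expect_true(all(cls$max_posterior > 0 & cls$max_posterior <= 1))
})

test_that("n_cc is capped by the usable rank with a warning", {
  fx <- make_transfer_fixture()
  expect_warning(
    emb <- cca_integrate(fx$ref_expr, fx$q_expr, fx$shared[1:8], n_cc = 20),
    "n_cc reduced"
  )
  expect_lte(ncol(emb$ref), 8)
  expect_error(cca_integrate(fx$ref_expr, fx$q_expr, "g1"), "shared genes")
})

test_that("Gaussian naive Bayes assigns centroids and survives tiny classes", {
  set.seed(43)
  ref_emb <- rbind(matrix(rnorm(50 * 4, 0), 50, 4),
                   matrix(rnorm(50 * 4, 3), 50, 4),
                   rep(-4, 4))    # single-cell class exactly at its centroid
  labels <- c(rep(1, 50), rep(2, 50), 3)
  query <- rbind(rep(0, 4), rep(3, 4), rep(-4, 4))    # the 3 centroids
  rownames(query) <- c("q1", "q2", "q3")
  cls <- nb_classify(list(ref = ref_emb, query = query), labels)
  expect_equal(cls$assigned_cluster, c(1, 2, 3))

  # agreement with an independent naive Bayes implementation
  set.seed(44)
  qbig <- matrix(rnorm(200 * 4, rep(c(0, 3), each = 100)), 200, 4)
  ours <- nb_classify(list(ref = ref_emb[1:100, ], query = qbig),
                      labels[1:100])
  fit <- e1071::naiveBayes(x = as.data.frame(ref_emb[1:100, ]),
                           y = factor(labels[1:100]))
  theirs <- predict(fit, as.data.frame(qbig))
  expect_gte(mean(as.integer(as.character(theirs)) ==
                    ours$assigned_cluster), 0.97)
})

test_that("transfer enrichment matches the hypergeometric oracle", {
  ann <- rep(c("typeA", "typeB"), each = 50)
  assigned <- c(rep(1, 45), rep(2, 5), rep(2, 48), rep(1, 2))
  res <- transfer_enrichment(ann, assigned)
  row <- res[res$annotation == "typeA" & res$cluster == 1, ]
  expect_equal(row$p, hypergeometric_test(100, 50, 47, 45))
  expect_equal(res$p_adj, pmin(1, res$p * nrow(res)))
  expect_lt(row$p_adj, 1e-10)
  expect_error(transfer_enrichment(character(0), integer(0)), "empty")
})

test_that("uniform annotations are not spuriously enriched", {
  set.seed(45)
  flags <- 0
  for (i in 1:20) {
    ann <- sample(c("x", "y"), 300, replace = TRUE)
    assigned <- sample(1:3, 300, replace = TRUE)
    res <- transfer_enrichment(ann, assigned)
    flags <- flags + sum(res$p_adj < 0.05)
  }
  expect_lte(flags / (20 * 6), 0.05)
})

test_that("proportion table rows sum to one with complete cluster columns", {
  fx <- make_transfer_fixture()
  tab <- proportion_table(fx$q$meta, fx$q$truth$clusters$cluster)
  sums <- tapply(tab$proportion, tab$donor, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(nrow(tab), length(unique(tab$donor)) * 3)
  expect_true(all(tab$proportion >= 0 & tab$proportion <= 1))
})

test_that("group model recovers a planted depletion and validates input", {
  fx <- make_transfer_fixture(seed = 46, depletion = 0.6, n_query = 3000)
  tab <- proportion_table(fx$q$meta, fx$q$truth$clusters$cluster)
  res <- proportion_group_model(tab, case_group = "case")
  hit <- res[res$cluster == 2, ]
  expect_lt(hit$coefficient, 0)
  expect_lt(hit$conf_high, 0)
  expect_equal(res$p_adj, pmin(1, res$p * 3))

  solo <- dplyr::mutate(tab, group = "case")
  expect_error(proportion_group_model(solo), "two donor groups")
})

test_that("non-parametric proportion test flags separated clusters only", {
  fx <- make_transfer_fixture(seed = 47, depletion = 0.9, n_query = 4000)
  tab <- proportion_table(fx$q$meta, fx$q$truth$clusters$cluster)
  res <- proportion_nonparametric_test(tab)
  expect_true(res$significant[res$cluster == 2])
  res_kw <- proportion_nonparametric_test(tab, method = "kruskal")
  expect_equal(res$p, res_kw$p, tolerance = 0.05)

  single <- tab[tab$donor %in% c(unique(tab$donor)[1:3]), ]
  single$group <- c("case", "control", "control")[
    match(single$donor, unique(single$donor))]
  expect_warning(proportion_nonparametric_test(single), "single donor")
})
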