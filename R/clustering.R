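# Core algorithm: grid-searched PCA-Louvain clustering gated by random-forest
# robustness, with merging of unrobust clusters and recursive subclustering.

# Centered (not scaled) PCA coordinates via eigen-decomposition of the
# smaller Gram matrix.
pca_embed <- function(x, n_pcs) {
  x <- as.matrix(x)
  if (n_pcs >= min(dim(x))) {
    stop("n_pcs must be smaller than both the number of cells and genes")
  }
  xc <- sweep(x, 2, colMeans(x))
  if (ncol(xc) <= nrow(xc)) {
    ev <- eigen(crossprod(xc), symmetric = TRUE)
    scores <- xc %*% ev$vectors[, seq_len(n_pcs), drop = FALSE]
  } else {
    ev <- eigen(tcrossprod(xc), symmetric = TRUE)
    u <- ev$vectors[, seq_len(n_pcs), drop = FALSE]
    scores <- sweep(u, 2, sqrt(pmax(ev$values[seq_len(n_pcs)], 0)), "*")
  }
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  scores
}

# Shared-nearest-neighbour graph: k nearest neighbours by Euclidean distance
# in PC space, edges weighted by the Jaccard overlap of the two cells'
# neighbour sets (each set includes the cell itself).
snn_graph <- function(pcs, k = 20) {
  n <- nrow(pcs)
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(pcs))
  nn <- matrix(0L, n, k + 1)
  for (i in seq_len(n)) {
    nn[i, ] <- order(d[i, ])[seq_len(k + 1)]   # self is nearest (distance 0)
  }
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k + 1), j = as.vector(t(nn)), x = 1,
    dims = c(n, n)
  )
  shared <- Matrix::tcrossprod(adj)
  tri <- methods::as(Matrix::triu(shared, k = 1), "TsparseMatrix")
  w <- tri@x / (2 * (k + 1) - tri@x)     # Jaccard: shared / union of sets
  keep <- w >= 1 / 15                    # prune negligible overlaps
  igraph::graph_from_data_frame(
    data.frame(from = tri@i[keep] + 1L, to = tri@j[keep] + 1L,
               weight = w[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
}

louvain_labels <- function(graph, resolution, seed) {
  set.seed(seed)
  comm <- igraph::cluster_louvain(graph, resolution = resolution)
  as.integer(igraph::membership(comm))
}

rf_fit <- function(features, labels, num_trees, seed) {
  ranger::ranger(
    x = as.data.frame(features), y = labels,
    num.trees = num_trees, seed = seed, num.threads = 1,
    verbose = FALSE
  )
}

rf_predict <- function(fit, features) {
  predict(fit, as.data.frame(features), num.threads = 1)$predictions
}

#' Cluster cells once with PCA-Louvain
#'
#' Centered PCA to `n_pcs` components, a k-nearest-neighbour graph in PC
#' space with shared-nearest-neighbour Jaccard edge weights, then Louvain
#' modularity optimization at the given resolution. Deterministic given
#' `seed`.
#'
#' @param x cells x genes matrix (batch-corrected residuals restricted to
#'   variable genes).
#' @param n_pcs number of principal components (< min(cells, genes)).
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed.
#' @param knn_k neighbours for the graph (reduced with a warning when there
#'   are fewer cells).
#' @return integer vector of cluster labels, one per cell.
#' @export
cluster_once <- function(x, n_pcs, resolution, seed = 1L, knn_k = 20) {
  pcs <- pca_embed(x, n_pcs)
  if (knn_k > nrow(pcs) - 1) {
    warning("knn_k reduced to ", nrow(pcs) - 1, " (fewer cells than k)")
    knn_k <- nrow(pcs) - 1
  }
  g <- snn_graph(pcs, knn_k)
  louvain_labels(g, resolution, seed)
}

# Stratified train/test split: per cluster, about train_frac of the cells in
# the training set, with at least one cell on each side for clusters of
# size >= 2. Singleton clusters go entirely to training (they cannot be
# scored and are reported as unrobust by the caller).
stratified_split <- function(labels, train_frac) {
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_c <- length(idx)
    if (n_c == 1) {
      train[idx] <- TRUE
      next
    }
    n_train <- max(1, min(n_c - 1, round(n_c * train_frac)))
    train[sample(idx, n_train)] <- TRUE
  }
  train
}

#' Assess cluster robustness with a held-out random-forest classifier
#'
#' For each of `n_iter` stratified splits, a random forest is trained on the
#' training cells' PC coordinates and predicts the held-out cells; the
#' per-cluster accuracy of a split is the fraction of that cluster's test
#' cells predicted correctly. The report carries each cluster's minimum
#' accuracy over the iterations (the robustness gate statistic) and the
#' pooled confusion tallies of misclassified test cells.
#'
#' @param features cells x d matrix of PC coordinates.
#' @param labels integer cluster labels (>= 2 distinct clusters).
#' @param n_iter number of splits.
#' @param train_frac training fraction per split.
#' @param seed integer seed.
#' @param num_trees trees per forest.
#' @return object of class `mgpop_robustness`: list with `per_cluster`
#'   tibble (`cluster`, `n_cells`, `min_accuracy`, `mean_accuracy`),
#'   `accuracy` (iterations x clusters matrix) and `confusion` (true x
#'   predicted misclassification tallies).
#' @export
assess_robustness <- function(features, labels, n_iter = 20,
                              train_frac = 0.5, seed = 1L, num_trees = 100) {
  labels <- as.integer(labels)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("robustness assessment needs >= 2 clusters")
  k <- length(clusters)
  fac <- factor(labels, levels = clusters)
  acc <- matrix(NA_real_, n_iter, k, dimnames = list(NULL, clusters))
  confusion <- matrix(0, k, k, dimnames = list(clusters, clusters))
  singleton <- tabulate(match(labels, clusters), k) == 1
  for (i in seq_len(n_iter)) {
    it_seed <- derive_seed(seed, "robustness", i)
    set.seed(it_seed)
    train <- stratified_split(labels, train_frac)
    fit <- rf_fit(features[train, , drop = FALSE], fac[train],
                  num_trees, it_seed)
    pred <- rf_predict(fit, features[!train, , drop = FALSE])
    truth <- fac[!train]
    for (j in seq_len(k)) {
      in_cl <- truth == clusters[j]
      if (any(in_cl)) acc[i, j] <- mean(pred[in_cl] == truth[in_cl])
    }
    wrong <- pred != truth
    if (any(wrong)) {
      tw <- table(truth[wrong], pred[wrong])
      confusion[rownames(tw), colnames(tw)] <-
        confusion[rownames(tw), colnames(tw)] + tw
    }
  }
  safe_min <- function(a) if (all(is.na(a))) 0 else min(a, na.rm = TRUE)
  safe_mean <- function(a) if (all(is.na(a))) 0 else mean(a, na.rm = TRUE)
  min_acc <- apply(acc, 2, safe_min)
  min_acc[singleton] <- 0  # unscorable singleton clusters are unrobust
  per_cluster <- tibble(
    cluster = clusters,
    n_cells = as.integer(tabulate(match(labels, clusters), k)),
    min_accuracy = unname(min_acc),
    mean_accuracy = unname(apply(acc, 2, safe_mean))
  )
  structure(
    list(per_cluster = per_cluster, accuracy = acc, confusion = confusion,
         n_iter = n_iter, train_frac = train_frac),
    class = "mgpop_robustness"
  )
}

#' @export
print.mgpop_robustness <- function(x, ...) {
  cat(sprintf("<mgpop_robustness> %d clusters, %d iterations\n",
              nrow(x$per_cluster), x$n_iter))
  print(x$per_cluster)
  invisible(x)
}

# Pick the merge destination for an unrobust cluster: the cluster receiving
# most of its misclassified test cells; ties broken by cluster size then
# lower id; fallback (no confusion recorded) is the nearest centroid.
merge_target <- function(cluster, report, labels, features) {
  row <- report$confusion[as.character(cluster), ]
  row <- row[names(row) != as.character(cluster)]
  if (any(row > 0)) {
    cand <- names(row)[row == max(row)]
    if (length(cand) > 1) {
      sizes <- vapply(cand, function(cl) sum(labels == as.integer(cl)), 0)
      cand <- cand[sizes == max(sizes)]
    }
    return(as.integer(min(as.integer(cand))))
  }
  others <- setdiff(sort(unique(labels)), cluster)
  cen <- vapply(others, function(cl) {
    colMeans(features[labels == cl, , drop = FALSE])
  }, numeric(ncol(features)))
  own <- colMeans(features[labels == cluster, , drop = FALSE])
  others[which.min(colSums((cen - own)^2))]
}

#' Merge clusters failing the robustness gate
#'
#' While any cluster's minimum held-out prediction accuracy is strictly
#' below `accuracy_threshold`, the lowest-accuracy cluster is absorbed into
#' the cluster receiving most of its misclassified test cells, and
#' robustness is re-assessed. Stops when all clusters pass the gate or one
#' cluster remains. A minimum accuracy of exactly the threshold passes
#' (the gate is "strictly below").
#'
#' @inheritParams assess_robustness
#' @param report optional precomputed [assess_robustness()] result for the
#'   initial labels.
#' @param accuracy_threshold robustness gate (default 0.75).
#' @return list with `labels` (merged integer labels), `history` tibble
#'   (`step`, `from`, `to`, `min_accuracy`) and `report` (final robustness
#'   report, `NULL` when one cluster remains).
#' @export
merge_unrobust <- function(features, labels, accuracy_threshold = 0.75,
                           n_iter = 20, train_frac = 0.5, seed = 1L,
                           num_trees = 100, report = NULL) {
  labels <- as.integer(labels)
  history <- list()
  step <- 0L
  repeat {
    if (length(unique(labels)) < 2) {
      report <- NULL
      break
    }
    if (is.null(report)) {
      report <- assess_robustness(features, labels, n_iter, train_frac,
                                  derive_seed(seed, "merge", step), num_trees)
    }
    pc <- report$per_cluster
    worst <- pc$cluster[which.min(pc$min_accuracy)]
    worst_acc <- min(pc$min_accuracy)
    if (worst_acc >= accuracy_threshold) break
    target <- merge_target(worst, report, labels, features)
    step <- step + 1L
    history[[step]] <- tibble(step = step, from = worst, to = target,
                              min_accuracy = worst_acc)
    labels[labels == worst] <- target
    report <- NULL
  }
  list(labels = labels,
       history = if (length(history)) bind_rows(history) else
         tibble(step = integer(), from = integer(), to = integer(),
                min_accuracy = double()),
       report = report)
}

relabel_by_size <- function(labels) {
  sizes <- sort(table(labels), decreasing = TRUE)
  match(as.character(labels), names(sizes))
}

#' Grid search over principal components and Louvain resolutions
#'
#' For every combination of `pc_grid` and `resolution_grid`, clusters the
#' cells, applies the random-forest robustness gate with merging, and counts
#' the surviving clusters of size at least `min_cluster_size`. The
#' combination yielding the largest number of robust clusters is selected
#' (ties: fewest PCs, then lowest resolution). The PCA is computed once at
#' the largest PC count and sliced; identical partitions arising at
#' different resolutions share one robustness assessment.
#'
#' @param x cells x genes matrix (residuals restricted to variable genes).
#' @param config a [pipeline_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return list with `labels` (integer labels renumbered by decreasing
#'   size), `selection` tibble (one row per grid point: `n_pcs`,
#'   `resolution`, `n_initial`, `n_robust`, `selected`), `best` (list:
#'   `n_pcs`, `resolution`, `report`, `history`) and `pcs` (the selected PC
#'   coordinates).
#' @export
grid_search <- function(x, config = pipeline_config(), seed = config$seed) {
  x <- as.matrix(x)
  pc_grid <- config$pc_grid[config$pc_grid < min(dim(x))]
  if (!length(pc_grid)) {
    stop("no usable PC counts: matrix is ", nrow(x), " x ", ncol(x))
  }
  pca_full <- pca_embed(x, max(pc_grid))
  knn_k <- min(config$knn_k, nrow(x) - 1)
  memo <- new.env(parent = emptyenv())
  rows <- list()
  results <- list()
  for (n_pcs in pc_grid) {
    pcs <- pca_full[, seq_len(n_pcs), drop = FALSE]
    g <- snn_graph(pcs, knn_k)
    for (res in config$resolution_grid) {
      lab0 <- louvain_labels(g, res,
                             derive_seed(seed, "louvain",
                                         n_pcs * 1000L + round(res * 100)))
      key <- paste(n_pcs, paste(match(lab0, unique(lab0)), collapse = ","),
                   sep = "|")
      if (is.null(memo[[key]])) {
        if (length(unique(lab0)) < 2) {
          memo[[key]] <- list(labels = lab0,
                              history = NULL, report = NULL)
        } else {
          memo[[key]] <- merge_unrobust(
            pcs, lab0,
            accuracy_threshold = config$accuracy_threshold,
            n_iter = config$robustness_iters,
            train_frac = config$robustness_train_frac,
            seed = derive_seed(seed, "gate", n_pcs),
            num_trees = config$rf_num_trees
          )
        }
      }
      merged <- memo[[key]]
      sizes <- table(merged$labels)
      n_robust <- sum(sizes >= config$min_cluster_size)
      rows[[length(rows) + 1]] <- tibble(
        n_pcs = n_pcs, resolution = res,
        n_initial = length(unique(lab0)),
        n_robust = as.integer(max(n_robust, 1L))
      )
      results[[length(results) + 1]] <- merged
    }
  }
  selection <- bind_rows(rows)
  best_i <- order(-selection$n_robust, selection$n_pcs,
                  selection$resolution)[1]
  selection$selected <- seq_len(nrow(selection)) == best_i
  best <- results[[best_i]]
  best_pcs <- pca_full[, seq_len(selection$n_pcs[best_i]), drop = FALSE]
  list(
    labels = relabel_by_size(best$labels),
    selection = selection,
    best = list(n_pcs = selection$n_pcs[best_i],
                resolution = selection$resolution[best_i],
                report = best$report, history = best$history),
    pcs = best_pcs
  )
}

# Number of genes supporting a split between two cell groups: BH-adjusted
# rank-sum p below alpha AND an effect of at least lfc. For counts the
# effect is the absolute log2 fold change of mean CPM (pseudocount 1). For
# arbitrary expression values it is the standardized mean difference
# (pooled SD units) against a fixed floor of 3: a cut through a homogeneous
# population projects to per-feature standardized differences well below 2,
# while genuinely separated groups differ by several SD in their
# discriminating features.
de_support <- function(x, in_a, alpha = 0.05, lfc = 1, counts = TRUE) {
  if (counts) {
    tot <- Matrix::rowSums(x)
    m <- as.matrix(x) * (1e6 / tot)
    m <- m[, Matrix::colSums(x) > 0, drop = FALSE]
  } else {
    m <- as.matrix(x)
  }
  pv <- rank_sum_pvalues(m, in_a)
  padj <- p.adjust(pv, method = "BH")
  mu_a <- colMeans(m[in_a, , drop = FALSE])
  mu_b <- colMeans(m[!in_a, , drop = FALSE])
  if (counts) {
    eff <- abs(log2((mu_a + 1) / (mu_b + 1)))
    floor_eff <- lfc
  } else {
    va <- apply(m[in_a, , drop = FALSE], 2, var)
    vb <- apply(m[!in_a, , drop = FALSE], 2, var)
    pooled <- sqrt((va + vb) / 2)
    pooled[pooled == 0] <- 1
    eff <- abs(mu_a - mu_b) / pooled
    floor_eff <- 3
  }
  sum(padj < alpha & eff >= floor_eff, na.rm = TRUE)
}

# Iteratively merge sibling subclusters whose split lacks gene-level
# support: held-out classifier accuracy cannot reject a clean geometric cut
# through a homogeneous population, so every surviving sibling pair must
# differ in at least min_genes supporting genes.
merge_unsupported <- function(labels, x, alpha, lfc, min_genes,
                              counts = TRUE) {
  if (min_genes <= 0) return(labels)
  repeat {
    cls <- sort(unique(labels))
    if (length(cls) < 2) break
    pairs <- utils::combn(cls, 2)
    nde <- apply(pairs, 2, function(p) {
      idx <- labels %in% p
      de_support(x[idx, , drop = FALSE], labels[idx] == p[1],
                 alpha, lfc, counts)
    })
    if (min(nde) >= min_genes) break
    p <- pairs[, which.min(nde)]
    labels[labels == p[2]] <- p[1]
  }
  labels
}

# Absorb clusters smaller than min_size into the nearest cluster by centroid
# distance in the given feature space.
absorb_small_clusters <- function(labels, features, min_size) {
  repeat {
    sizes <- table(labels)
    if (length(sizes) < 2 || min(sizes) >= min_size) break
    small <- as.integer(names(sizes)[which.min(sizes)])
    others <- as.integer(names(sizes)[names(sizes) != as.character(small)])
    cen <- vapply(others, function(cl) {
      colMeans(features[labels == cl, , drop = FALSE])
    }, numeric(ncol(features)))
    own <- colMeans(features[labels == small, , drop = FALSE])
    labels[labels == small] <- others[which.min(colSums((cen - own)^2))]
  }
  labels
}

#' Iterative subclustering
#'
#' Runs [grid_search()] on all cells, then recursively re-runs the whole
#' procedure (variable genes and PCA recomputed within the subset) on each
#' resulting cluster, until a subset yields a single robust cluster or is
#' smaller than twice the minimum cluster size. Final flat labels are the
#' leaves, renumbered by decreasing size; leaves smaller than the minimum
#' cluster size are absorbed into the nearest leaf by centroid distance.
#'
#' When counts are available (input is a [preprocess()] result), an
#' accepted split must additionally be supported at the gene level: each
#' pair of sibling subclusters must differ in at least
#' `config$min_de_genes` genes (BH-adjusted rank-sum p below
#' `config$de_alpha` and absolute log2 CPM fold change of at least
#' `config$de_lfc`); unsupported pairs are merged before recursion. A
#' held-out classifier can learn any clean geometric cut through a
#' homogeneous population, so classifier accuracy alone does not terminate
#' the recursion; a real subdivision of a cell population must be visible
#' in individual genes.
#'
#' @param x a `mgpop_prep` list from [preprocess()] (variable genes are then
#'   selected per node from the counts), or a bare cells x genes residual
#'   matrix (variable genes selected from the matrix itself).
#' @param config a [pipeline_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return object of class `mgpop_cluster_tree`: list with `labels` tibble
#'   (`cell_id`, `cluster`, `path`), `nodes` tibble (`path`, `n_cells`,
#'   `n_pcs`, `resolution`, `n_children`, `depth`), `selections` (per-node
#'   grid records) and `config`.
#' @export
iterative_subcluster <- function(x, config = pipeline_config(),
                                 seed = config$seed) {
  if (inherits(x, "mgpop_prep")) {
    expr <- as.matrix(x$residual)
    vg_source <- as.matrix(x$counts)
    counts_src <- x$counts
  } else {
    expr <- as.matrix(x)
    vg_source <- expr
    counts_src <- NULL        # split support then uses the values directly
  }
  n <- nrow(expr)
  cell_ids <- rownames(expr) %||% as.character(seq_len(n))
  paths <- character(n)
  nodes <- list()
  selections <- list()

  recurse <- function(idx, path, depth) {
    sub <- expr[idx, , drop = FALSE]
    leaf <- function() {
      nodes[[length(nodes) + 1]] <<- tibble(
        path = path, n_cells = length(idx), n_pcs = NA_integer_,
        resolution = NA_real_, n_children = 0L, depth = depth
      )
      paths[idx] <<- path
    }
    if (length(idx) < 2 * config$min_cluster_size) return(leaf())
    vg <- select_variable_genes(vg_source[idx, , drop = FALSE])
    vg <- intersect(vg, colnames(sub))
    if (length(vg) <= min(config$pc_grid)) return(leaf())
    gs <- grid_search(sub[, vg, drop = FALSE], config,
                      seed = derive_seed(seed, path))
    selections[[path]] <<- gs$selection
    labs <- gs$labels
    if (is.null(counts_src)) {
      labs <- merge_unsupported(labs, sub, config$de_alpha, config$de_lfc,
                                config$min_de_genes, counts = FALSE)
    } else {
      labs <- merge_unsupported(labs, counts_src[idx, , drop = FALSE],
                                config$de_alpha, config$de_lfc,
                                config$min_de_genes)
    }
    labs <- relabel_by_size(labs)
    k <- length(unique(labs))
    if (k < 2) return(leaf())
    nodes[[length(nodes) + 1]] <<- tibble(
      path = path, n_cells = length(idx), n_pcs = gs$best$n_pcs,
      resolution = gs$best$resolution, n_children = k, depth = depth
    )
    for (j in seq_len(k)) {
      recurse(idx[labs == j], paste(path, j, sep = "."), depth + 1L)
    }
  }
  recurse(seq_len(n), "root", 0L)

  leaf_ids <- match(paths, names(sort(table(paths), decreasing = TRUE)))
  leaf_ids <- absorb_small_clusters(leaf_ids, expr, config$min_cluster_size)
  final <- relabel_by_size(leaf_ids)
  structure(
    list(
      labels = tibble(cell_id = cell_ids, cluster = final, path = paths),
      nodes = bind_rows(nodes),
      selections = selections,
      config = config
    ),
    class = "mgpop_cluster_tree"
  )
}

#' @export
print.mgpop_cluster_tree <- function(x, ...) {
  cat(sprintf("<mgpop_cluster_tree> %d cells, %d clusters, depth %d\n",
              nrow(x$labels), length(unique(x$labels$cluster)),
              max(x$nodes$depth)))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.mgpop_cluster_tree <- function(x, ...) {
  x$labels |>
    group_by(.data$cluster) |>
    summarise(n_cells = n(), path = .data$path[1], .groups = "drop") |>
    arrange(.data$cluster)
}

#' @export
glance.mgpop_cluster_tree <- function(x, ...) {
  tibble(
    n_cells = nrow(x$labels),
    n_clusters = length(unique(x$labels$cluster)),
    max_depth = max(x$nodes$depth),
    n_nodes = nrow(x$nodes)
  )
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement (Hubert-Arabie form) computed from the
#' contingency table of the two labelings.
#'
#' @param labels_a,labels_b two partitions of the same items.
#' @return a number in `[-1, 1]`; 1 for identical partitions.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))
adjusted_rand_index <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Single-donor clustering concordance
#'
#' Re-runs the full pipeline (preprocessing and iterative subclustering) on
#' each donor's cells alone and reports the Adjusted Rand Index between the
#' donor-restricted full-data labels and the donor-only labels. Donors with
#' fewer than twice the minimum cluster size cells (after QC) are skipped
#' with a warning.
#'
#' @param counts cells x genes count matrix (pre-QC).
#' @param meta per-cell metadata with `cell_id` and `batch`.
#' @param full_labels tibble with `cell_id` and `cluster` from the full-data
#'   clustering.
#' @param config a [pipeline_config()].
#' @return tibble with `donor`, `n_cells`, `n_clusters_donor`, `ari`.
#' @export
single_donor_concordance <- function(counts, meta, full_labels,
                                     config = pipeline_config()) {
  out <- list()
  for (d in unique(meta$donor)) {
    cells <- meta$cell_id[meta$donor == d]
    cells <- intersect(cells, rownames(counts))
    if (length(cells) < 2 * config$min_cluster_size) {
      warning("donor ", d, " skipped: too few cells")
      next
    }
    sub_meta <- meta[meta$cell_id %in% cells, , drop = FALSE]
    prep <- tryCatch(
      preprocess(counts[cells, , drop = FALSE], sub_meta, config),
      error = function(e) NULL
    )
    if (is.null(prep) || nrow(prep$residual) < 2 * config$min_cluster_size) {
      warning("donor ", d, " skipped: too few cells after QC")
      next
    }
    tree <- iterative_subcluster(prep, config,
                                 seed = derive_seed(config$seed, d))
    shared <- intersect(tree$labels$cell_id, full_labels$cell_id)
    a <- full_labels$cluster[match(shared, full_labels$cell_id)]
    b <- tree$labels$cluster[match(shared, tree$labels$cell_id)]
    out[[d]] <- tibble(
      donor = d, n_cells = length(shared),
      n_clusters_donor = length(unique(b)),
      ari = adjusted_rand_index(a, b)
    )
  }
  bind_rows(out)
}
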