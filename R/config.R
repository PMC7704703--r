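#' Pipeline configuration
#'
#' Collects every numeric parameter of the clustering/validation pipeline in
#' one place. Defaults encode the analysis settings the pipeline was built
#' around: a strict
#' UMI window of (1000, 10000) for cell QC, a grid of 5--15 principal
#' components crossed with Louvain resolutions 0.2/0.4/0.6/0.8, a
#' random-forest robustness gate requiring minimum held-out prediction
#' accuracy of 0.75 over 20 stratified half-splits, a minimum cluster size of
#' 8 cells, constellation analysis with 100 repetitions of 4-fold
#' cross-validation and an ambiguity cutoff of 75 correct assignments, top-50
#' signature genes, and a mean + 2 SD marker-high gate.
#'
#' @param min_umi,max_umi exclusive bounds on per-cell total UMI for QC.
#' @param pc_grid integer vector of principal-component counts to try.
#' @param resolution_grid Louvain resolution parameters to try.
#' @param robustness_iters number of train/test splits per robustness
#'   assessment.
#' @param robustness_train_frac fraction of cells used for training in each
#'   robustness split.
#' @param accuracy_threshold minimum per-cluster held-out prediction accuracy;
#'   clusters strictly below it are merged.
#' @param min_cluster_size smallest cluster counted as a valid cluster.
#' @param constellation_reps repetitions of cross-validated classification per
#'   cluster pair.
#' @param constellation_train_frac training fraction for the pairwise
#'   classifier (0.75 corresponds to 4-fold cross-validation).
#' @param ambiguity_threshold a cell correctly assigned in at most this many
#'   repetitions (out of `constellation_reps`) is called intermediate.
#' @param signature_top_n number of top-ranked genes kept per cluster
#'   signature.
#' @param de_alpha adjusted-p significance level for pairwise differential
#'   expression.
#' @param min_de_genes minimum number of supporting differentially expressed
#'   genes (adjusted p below `de_alpha` and at least `de_lfc` absolute log2
#'   fold change in CPM) a pair of sibling subclusters must show to remain
#'   split during iterative subclustering; held-out classifier accuracy
#'   alone cannot reject clean geometric cuts through a homogeneous cell
#'   population, so an accepted split must also be supported at the gene
#'   level.
#' @param de_lfc absolute log2 fold-change floor for a supporting gene.
#' @param high_expressor_sd number of standard deviations above the mean for
#'   the marker-high intensity gate.
#' @param n_cc number of canonical components for cross-dataset integration.
#' @param knn_k neighbours for the shared-nearest-neighbour graph.
#' @param rf_num_trees trees per random forest.
#' @param seed integer seed from which all stochastic stages derive their
#'   streams.
#'
#' @return A list of class `mgpop_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(seed = 1)
#' cfg$accuracy_threshold
pipeline_config <- function(min_umi = 1000,
                            max_umi = 10000,
                            pc_grid = 5:15,
                            resolution_grid = c(0.2, 0.4, 0.6, 0.8),
                            robustness_iters = 20,
                            robustness_train_frac = 0.5,
                            accuracy_threshold = 0.75,
                            min_cluster_size = 8,
                            constellation_reps = 100,
                            constellation_train_frac = 0.75,
                            ambiguity_threshold = 75,
                            signature_top_n = 50,
                            de_alpha = 0.05,
                            min_de_genes = 10,
                            de_lfc = 1.0,
                            high_expressor_sd = 2.0,
                            n_cc = 20,
                            knn_k = 20,
                            rf_num_trees = 100,
                            seed = 1L) {
  cfg <- list(
    min_umi = min_umi, max_umi = max_umi,
    pc_grid = as.integer(pc_grid), resolution_grid = resolution_grid,
    robustness_iters = as.integer(robustness_iters),
    robustness_train_frac = robustness_train_frac,
    accuracy_threshold = accuracy_threshold,
    min_cluster_size = as.integer(min_cluster_size),
    constellation_reps = as.integer(constellation_reps),
    constellation_train_frac = constellation_train_frac,
    ambiguity_threshold = ambiguity_threshold,
    signature_top_n = as.integer(signature_top_n),
    de_alpha = de_alpha,
    min_de_genes = as.integer(min_de_genes),
    de_lfc = de_lfc,
    high_expressor_sd = high_expressor_sd,
    n_cc = as.integer(n_cc),
    knn_k = as.integer(knn_k),
    rf_num_trees = as.integer(rf_num_trees),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$min_umi > 0, cfg$max_umi > cfg$min_umi,
    length(cfg$pc_grid) > 0, all(cfg$pc_grid >= 1),
    length(cfg$resolution_grid) > 0, all(cfg$resolution_grid > 0),
    cfg$robustness_iters >= 1,
    cfg$robustness_train_frac > 0, cfg$robustness_train_frac < 1,
    cfg$accuracy_threshold > 0, cfg$accuracy_threshold <= 1,
    cfg$min_cluster_size >= 1,
    cfg$constellation_reps >= 1,
    cfg$constellation_train_frac > 0, cfg$constellation_train_frac < 1,
    cfg$ambiguity_threshold >= 0,
    cfg$signature_top_n >= 0,
    cfg$de_alpha > 0, cfg$de_alpha < 1,
    cfg$min_de_genes >= 0, cfg$de_lfc >= 0,
    cfg$high_expressor_sd > 0,
    cfg$n_cc >= 1, cfg$knn_k >= 1, cfg$rf_num_trees >= 1
  )
  structure(cfg, class = "mgpop_config")
}

#' @export
print.mgpop_config <- function(x, ...) {
  cat("<mgpop_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

# Derive a reproducible sub-seed below 2^31 for a named stage.
derive_seed <- function(seed, stage, index = 0L) {
  base <- sum(utf8ToInt(stage)) %% 10000L
  as.integer((as.numeric(seed) * 48271 + base * 7919 + index * 104729) %% 2147483647)
}

config_hash <- function(cfg) {
  rlang::hash(unclass(cfg))
}
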