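#' Synthetic-data configuration
#'
#' Parameters of the droplet-UMI simulator used to exercise the pipeline with
#' known ground truth. Counts are gamma-Poisson (negative binomial) around
#' cell-specific library sizes and cluster-specific expression profiles.
#' Cluster structure mimics the population model the pipeline targets: a
#' large homeostatic "core" cluster whose designated satellite clusters have
#' mean profiles interpolated toward the core (a radial continuum), plus
#' well-separated distal clusters. Each donor is its own batch; batch effects
#' multiply a random subset of gene means. Library sizes are log-normal with
#' tails on both sides of the (1000, 10000) QC window so the QC filter has a
#' nontrivial effect.
#'
#' @param n_cells,n_genes matrix dimensions before QC.
#' @param n_clusters number of planted clusters.
#' @param cluster_proportions sampling proportions (default equal); must sum
#'   to 1.
#' @param n_markers_per_cluster planted marker genes per cluster (disjoint
#'   across clusters).
#' @param marker_log2fc log2 fold-change of a marker in its own cluster.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   relative gene expression.
#' @param marker_meanlog,marker_sdlog log-normal parameters of marker-gene
#'   baseline expression (markers are drawn from the well-expressed range, as
#'   real cell-type markers are).
#' @param lib_meanlog,lib_sdlog log-normal library-size distribution
#'   (defaults give median 2500 UMI with roughly one percent of cells
#'   outside the QC window).
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param n_donors donors; one donor = one batch.
#' @param batch_scale SD of the log-normal multiplicative batch effect.
#' @param batch_gene_frac fraction of genes perturbed per batch.
#' @param core_cluster_index index of the homeostatic core cluster.
#' @param satellite_clusters clusters whose profiles are pulled toward the
#'   core.
#' @param satellite_weight mixing weight toward the core profile (0 = no
#'   pull).
#' @param seed integer seed; all generators are deterministic given it.
#' @return list of class `mgpop_sim_config`.
#' @export
sim_config <- function(n_cells = 2000,
                       n_genes = 2000,
                       n_clusters = 6,
                       cluster_proportions = NULL,
                       n_markers_per_cluster = 25,
                       marker_log2fc = 2.0,
                       baseline_meanlog = 0,
                       baseline_sdlog = 1.5,
                       marker_meanlog = 0.7,
                       marker_sdlog = 0.5,
                       lib_meanlog = log(2500),
                       lib_sdlog = 0.4,
                       dispersion = 2,
                       n_donors = 8,
                       batch_scale = 0.15,
                       batch_gene_frac = 0.2,
                       core_cluster_index = 1,
                       satellite_clusters = c(2, 3),
                       satellite_weight = 0.2,
                       seed = 1L) {
  if (is.null(cluster_proportions)) {
    cluster_proportions <- rep(1 / n_clusters, n_clusters)
  }
  cfg <- list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    n_clusters = as.integer(n_clusters),
    cluster_proportions = cluster_proportions,
    n_markers_per_cluster = as.integer(n_markers_per_cluster),
    marker_log2fc = marker_log2fc,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    marker_meanlog = marker_meanlog, marker_sdlog = marker_sdlog,
    lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog,
    dispersion = dispersion,
    n_donors = as.integer(n_donors),
    batch_scale = batch_scale, batch_gene_frac = batch_gene_frac,
    core_cluster_index = as.integer(core_cluster_index),
    satellite_clusters = as.integer(satellite_clusters),
    satellite_weight = satellite_weight,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_cells >= 1, cfg$n_genes >= 1, cfg$n_clusters >= 1,
    length(cfg$cluster_proportions) == cfg$n_clusters,
    abs(sum(cfg$cluster_proportions) - 1) < 1e-9,
    all(cfg$cluster_proportions > 0),
    cfg$dispersion > 0, cfg$n_donors >= 1,
    cfg$batch_gene_frac >= 0, cfg$batch_gene_frac <= 1,
    cfg$core_cluster_index >= 1, cfg$core_cluster_index <= cfg$n_clusters,
    all(cfg$satellite_clusters >= 1 & cfg$satellite_clusters <= cfg$n_clusters),
    !(cfg$core_cluster_index %in% cfg$satellite_clusters),
    cfg$satellite_weight >= 0, cfg$satellite_weight < 1
  )
  if (cfg$n_markers_per_cluster * cfg$n_clusters > cfg$n_genes) {
    stop("n_markers_per_cluster * n_clusters exceeds n_genes")
  }
  structure(cfg, class = "mgpop_sim_config")
}

# Cluster expression profiles (genes x clusters, columns sum to 1) plus
# marker bookkeeping, shared by reference and query simulation.
build_cluster_profiles <- function(config) {
  g <- config$n_genes
  k <- config$n_clusters
  w <- rlnorm(g, config$baseline_meanlog, config$baseline_sdlog)
  marker_idx <- matrix(
    sample.int(g, k * config$n_markers_per_cluster),
    nrow = config$n_markers_per_cluster
  )
  w[as.vector(marker_idx)] <-
    rlnorm(length(marker_idx), config$marker_meanlog, config$marker_sdlog)
  profiles <- matrix(w, nrow = g, ncol = k)
  for (j in seq_len(k)) {
    profiles[marker_idx[, j], j] <-
      profiles[marker_idx[, j], j] * 2^config$marker_log2fc
  }
  core <- config$core_cluster_index
  for (s in config$satellite_clusters) {
    profiles[, s] <- (1 - config$satellite_weight) * profiles[, s] +
      config$satellite_weight * profiles[, core]
  }
  profiles <- sweep(profiles, 2, colSums(profiles), "/")
  gene_ids <- sprintf("gene_%04d", seq_len(g))
  rownames(profiles) <- gene_ids
  markers <- lapply(seq_len(k), function(j) gene_ids[marker_idx[, j]])
  names(markers) <- paste0("cluster_", seq_len(k))
  list(profiles = profiles, markers = markers, gene_ids = gene_ids)
}

# Draw NB counts for cells with given cluster, donor-batch and library size.
draw_counts <- function(profiles, batch_factors, cluster, batch, libsize,
                        dispersion, cell_ids) {
  mu <- profiles[, cluster, drop = FALSE] * batch_factors[, batch, drop = FALSE]
  mu <- sweep(mu, 2, colSums(mu), "/")
  mu <- sweep(mu, 2, libsize, "*")
  counts <- matrix(
    rnbinom(length(mu), mu = as.vector(mu), size = dispersion),
    nrow = nrow(profiles)
  )
  dimnames(counts) <- list(rownames(profiles), cell_ids)
  Matrix::t(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"))
}

batch_effect_matrix <- function(n_genes, batch_names, scale, gene_frac) {
  f <- matrix(1, n_genes, length(batch_names),
              dimnames = list(NULL, batch_names))
  if (scale > 0 && gene_frac > 0) {
    n_hit <- round(gene_frac * n_genes)
    for (b in seq_along(batch_names)) {
      hit <- sample.int(n_genes, n_hit)
      f[hit, b] <- exp(rnorm(n_hit, 0, scale))
    }
  }
  f
}

donor_table <- function(donor_ids, prefix_group = c("control", "case")) {
  n <- length(donor_ids)
  grp <- rep(prefix_group, length.out = n)[sample.int(n)]
  tibble(
    donor = donor_ids,
    group = grp,
    age = round(rnorm(n, 75, 8)),
    sex = sample(c("F", "M"), n, replace = TRUE)
  )
}

#' Simulate a reference single-cell UMI dataset with known ground truth
#'
#' Generates a cells x genes count matrix under the model described in
#' [sim_config()], together with per-cell metadata (donor, batch, group, age,
#' sex) and the ground truth (true cluster per cell, marker gene lists,
#' cluster profiles).
#'
#' @param config a [sim_config()].
#' @return list with `counts` (sparse cells x genes), `meta` (tibble),
#'   `truth` (list: `clusters` tibble, `markers`, `profiles`, `config`).
#' @export
#' @examples
#' ref <- simulate_reference(sim_config(n_cells = 200, n_genes = 300,
#'                                      n_clusters = 3, seed = 7))
#' dim(ref$counts)
simulate_reference <- function(config = sim_config()) {
  stopifnot(inherits(config, "mgpop_sim_config"))
  set.seed(config$seed)
  prof <- build_cluster_profiles(config)
  donors <- sprintf("donor_%02d", seq_len(config$n_donors))
  dtab <- donor_table(donors)
  batch_f <- batch_effect_matrix(config$n_genes, donors,
                                 config$batch_scale, config$batch_gene_frac)
  n <- config$n_cells
  cell_ids <- sprintf("cell_%05d", seq_len(n))
  cl <- sample.int(config$n_clusters, n, replace = TRUE,
                   prob = config$cluster_proportions)
  dn <- sample.int(config$n_donors, n, replace = TRUE)
  lib <- rlnorm(n, config$lib_meanlog, config$lib_sdlog)
  counts <- draw_counts(prof$profiles, batch_f, cl, dn, lib,
                        config$dispersion, cell_ids)
  meta <- tibble(cell_id = cell_ids, donor = donors[dn], batch = donors[dn]) |>
    left_join(dtab, by = "donor")
  truth <- list(
    clusters = tibble(cell_id = cell_ids, cluster = cl),
    donors = dtab,
    markers = prof$markers,
    profiles = prof$profiles,
    config = config
  )
  list(counts = counts, meta = meta, truth = truth)
}

#' Simulate a query dataset sharing the reference cluster structure
#'
#' Draws cells from the same cluster-profile model as a reference simulated
#' by [simulate_reference()], with two differences: a global multiplicative
#' platform shift on gene means (log-normal with SD `shift_scale`), and, in
#' donors of the case group, the sampling proportion of one cluster
#' multiplied by `(1 - depletion_fraction)` and renormalized. This emulates a
#' single-nucleus dataset in which one population is depleted in disease.
#'
#' @param truth the `truth` element returned by [simulate_reference()].
#' @param n_cells number of query cells.
#' @param depleted_cluster cluster index depleted in the case group.
#' @param depletion_fraction fraction by which the depleted cluster's
#'   sampling proportion is reduced in cases (0 = no depletion).
#' @param n_donors query donors, split evenly into case/control.
#' @param shift_scale SD of the per-gene log-normal platform shift.
#' @param seed integer seed.
#' @return list with `counts`, `meta`, `truth` (as for
#'   [simulate_reference()], with `depletion` recorded).
#' @export
simulate_query <- function(truth, n_cells = 2000, depleted_cluster = 2,
                           depletion_fraction = 0.5, n_donors = 40,
                           shift_scale = 0.1, seed = 1L) {
  config <- truth$config
  k <- config$n_clusters
  if (!(depleted_cluster %in% seq_len(k))) {
    stop("unknown cluster id: ", depleted_cluster)
  }
  stopifnot(depletion_fraction >= 0, depletion_fraction <= 1)
  set.seed(as.integer(seed))
  shift <- exp(rnorm(config$n_genes, 0, shift_scale))
  profiles <- truth$profiles * shift
  profiles <- sweep(profiles, 2, colSums(profiles), "/")
  donors <- sprintf("qdonor_%02d", seq_len(n_donors))
  dtab <- donor_table(donors)
  batch_f <- batch_effect_matrix(config$n_genes, donors,
                                 config$batch_scale, config$batch_gene_frac)
  base_p <- config$cluster_proportions
  case_p <- base_p
  case_p[depleted_cluster] <- case_p[depleted_cluster] * (1 - depletion_fraction)
  case_p <- case_p / sum(case_p)
  cell_ids <- sprintf("qcell_%05d", seq_len(n_cells))
  dn <- sample.int(n_donors, n_cells, replace = TRUE)
  is_case <- dtab$group[dn] == "case"
  cl <- integer(n_cells)
  if (any(is_case)) {
    cl[is_case] <- sample.int(k, sum(is_case), replace = TRUE, prob = case_p)
  }
  if (any(!is_case)) {
    cl[!is_case] <- sample.int(k, sum(!is_case), replace = TRUE, prob = base_p)
  }
  lib <- rlnorm(n_cells, config$lib_meanlog, config$lib_sdlog)
  counts <- draw_counts(profiles, batch_f, cl, dn, lib,
                        config$dispersion, cell_ids)
  meta <- tibble(cell_id = cell_ids, donor = donors[dn], batch = donors[dn]) |>
    left_join(dtab, by = "donor")
  qtruth <- list(
    clusters = tibble(cell_id = cell_ids, cluster = cl),
    donors = dtab,
    markers = truth$markers,
    profiles = profiles,
    config = config,
    depletion = list(cluster = depleted_cluster,
                     fraction = depletion_fraction)
  )
  list(counts = counts, meta = meta, truth = qtruth)
}

#' Simulate a per-cell marker intensity table
#'
#' Emulates CellProfiler-style per-object measurements: a Gaussian base
#' population of marker intensities with an optional planted "high"
#' subpopulation shifted by `high_offset_sd` standard deviations, spread over
#' donors and images, with a base-marker positivity flag (e.g. the
#' pan-myeloid stain) and an optional plaque-proximity flag.
#'
#' @param n_cells total cells.
#' @param high_fraction fraction of base-positive cells planted as "high"
#'   (0 <= and < 1).
#' @param base_mean,base_sd Gaussian intensity parameters of the base
#'   population.
#' @param high_offset_sd offset of the high population mean, in base SD units.
#' @param n_donors,images_per_donor layout of cells over donors and images.
#' @param base_positive_frac probability a cell is base-marker positive.
#' @param plaque_frac probability a cell is plaque-proximal (0 disables the
#'   flag's use downstream).
#' @param high_plaque_or odds multiplier for a high cell to be
#'   plaque-proximal (1 = no topological association).
#' @param seed integer seed.
#' @return tibble with columns `cell_id`, `donor`, `image`, `intensity`,
#'   `base_positive`, `plaque_proximal`, `true_high`.
#' @export
simulate_intensity_table <- function(n_cells = 10000, high_fraction = 0.05,
                                     base_mean = 100, base_sd = 15,
                                     high_offset_sd = 4,
                                     n_donors = 10, images_per_donor = 20,
                                     base_positive_frac = 0.8,
                                     plaque_frac = 0, high_plaque_or = 1,
                                     seed = 1L) {
  stopifnot(high_fraction >= 0, high_fraction < 1, base_sd >= 0)
  set.seed(as.integer(seed))
  donor <- sprintf("donor_%02d", sample.int(n_donors, n_cells, replace = TRUE))
  image <- sprintf("%s_img_%02d", donor,
                   sample.int(images_per_donor, n_cells, replace = TRUE))
  base_positive <- runif(n_cells) < base_positive_frac
  true_high <- base_positive & runif(n_cells) < high_fraction
  intensity <- rnorm(n_cells, base_mean, base_sd)
  intensity[true_high] <- rnorm(sum(true_high),
                                base_mean + high_offset_sd * base_sd, base_sd)
  p_plaque <- rep(plaque_frac, n_cells)
  if (high_plaque_or != 1 && plaque_frac > 0) {
    odds <- plaque_frac / (1 - plaque_frac) * high_plaque_or
    p_plaque[true_high] <- odds / (1 + odds)
  }
  plaque_proximal <- runif(n_cells) < p_plaque
  tibble(
    cell_id = sprintf("obj_%06d", seq_len(n_cells)),
    donor = donor, image = image,
    intensity = intensity,
    base_positive = base_positive,
    plaque_proximal = plaque_proximal,
    true_high = true_high
  )
}

#' Simulate signed trait-association gene lists
#'
#' Emulates trait-association inputs: for each trait, a positively and a
#' negatively associated gene list. Under `design = "random"` both lists are
#' random draws from the gene universe (a null design). Under
#' `design = "planted"` the list of the given sign for the first trait is a
#' mixture of one cluster's marker genes (`marker_frac`) and random genes.
#'
#' @param truth the `truth` element of [simulate_reference()].
#' @param n_traits number of traits.
#' @param design `"random"` or `"planted"`.
#' @param planted_cluster cluster whose markers are planted (design
#'   `"planted"`).
#' @param planted_sign `+1` or `-1`: which directional list carries the
#'   planted markers.
#' @param marker_frac fraction of the planted list made of markers.
#' @param genes_per_list genes per directional list.
#' @param seed integer seed.
#' @return tibble with columns `trait`, `gene`, `sign` (+1/-1).
#' @export
simulate_trait_lists <- function(truth, n_traits = 5,
                                 design = c("random", "planted"),
                                 planted_cluster = 1, planted_sign = -1,
                                 marker_frac = 1, genes_per_list = 50,
                                 seed = 1L) {
  design <- match.arg(design)
  if (!length(design) || !n_traits) stop("empty trait design")
  stopifnot(planted_sign %in% c(-1, 1), marker_frac >= 0, marker_frac <= 1)
  set.seed(as.integer(seed))
  universe <- rownames(truth$profiles)
  out <- list()
  for (t in seq_len(n_traits)) {
    for (sgn in c(1, -1)) {
      if (design == "planted" && t == 1 && sgn == planted_sign) {
        markers <- truth$markers[[planted_cluster]]
        n_mark <- min(length(markers), round(marker_frac * genes_per_list))
        genes <- c(sample(markers, n_mark),
                   sample(setdiff(universe, markers),
                          genes_per_list - n_mark))
      } else {
        genes <- sample(universe, genes_per_list)
      }
      out[[length(out) + 1]] <- tibble(
        trait = sprintf("trait_%02d", t), gene = genes, sign = sgn
      )
    }
  }
  bind_rows(out)
}
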