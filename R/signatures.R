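# All-pairs differential expression and cluster-defining gene signatures.

# Vectorized two-sided Wilcoxon rank-sum test applied gene-wise to a
# cells x genes matrix. Normal approximation with tie correction and
# continuity correction; exact null distribution when both groups have at
# most 25 cells and the gene has no ties. Returns a p-value per gene
# (NA for untestable genes, e.g. constant in both groups).
rank_sum_pvalues <- function(m, in_group1, exact_max = 25) {
  n1 <- sum(in_group1)
  n2 <- sum(!in_group1)
  n <- n1 + n2
  use_exact <- n1 <= exact_max && n2 <= exact_max
  apply(m, 2, function(v) {
    r <- rank(v)
    w <- sum(r[in_group1]) - n1 * (n1 + 1) / 2   # Mann-Whitney U for group 1
    ties <- table(r)
    has_ties <- any(ties > 1)
    if (!has_ties && use_exact) {
      if (w > n1 * n2 / 2) {
        p <- 2 * (1 - pwilcox(w - 1, n1, n2))
      } else {
        p <- 2 * pwilcox(w, n1, n2)
      }
      return(min(1, p))
    }
    sigma2 <- (n1 * n2 / 12) *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(NA_real_)           # all values tied
    z <- w - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)     # continuity correction
    min(1, 2 * pnorm(-abs(z)))
  })
}

#' All-pairs differential expression between clusters
#'
#' For every unordered pair of clusters, tests each gene with a two-sided
#' Wilcoxon rank-sum test on counts-per-million (normal approximation with
#' tie and continuity corrections; exact distribution when both groups have
#' at most 25 cells and no ties), with Benjamini-Hochberg adjustment within
#' each pair's tested gene list. The effect direction is the sign of the
#' mean-CPM difference. Genes undetected in both groups of a pair are
#' excluded from that pair's testing universe.
#'
#' A negative-binomial regression test (the edgeR family) is the other
#' common choice for this step; the per-pair test is deliberately pluggable
#' and the rank-sum default is a robust, assumption-light one — the ranking
#' procedure built on top of it (up-comparison counts under the
#' never-downregulated constraint) is the part that defines the signatures.
#'
#' @param counts cells x genes un-normalized count matrix.
#' @param labels integer cluster labels (>= 2 clusters, each >= 2 cells).
#' @param alpha significance level recorded with the result.
#' @param test optional replacement test: `function(m, in_group1)` returning
#'   per-gene p-values for the cells x genes matrix `m`.
#' @return tibble of class `mgpop_de` with one row per (pair, testable
#'   gene): `cluster_a`, `cluster_b`, `gene`, `direction` (+1 up in
#'   `cluster_a`, -1 down, 0 tied means), `p`, `p_adj`.
#' @export
pairwise_de <- function(counts, labels, alpha = 0.05, test = NULL) {
  labels <- as.integer(labels)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("need >= 2 clusters")
  if (any(table(labels) < 2)) stop("every cluster needs >= 2 cells")
  test <- test %||% rank_sum_pvalues
  totals <- Matrix::rowSums(counts)
  cpm <- as.matrix(counts) * (1e6 / totals)
  pairs <- utils::combn(clusters, 2)
  out <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    idx <- which(labels %in% c(a, b))
    sub_counts <- counts[idx, , drop = FALSE]
    testable <- Matrix::colSums(sub_counts) > 0
    m <- cpm[idx, testable, drop = FALSE]
    in_a <- labels[idx] == a
    pv <- test(m, in_a)
    dir <- sign(colMeans(m[in_a, , drop = FALSE]) -
                  colMeans(m[!in_a, , drop = FALSE]))
    ok <- !is.na(pv)
    out[[p]] <- tibble(
      cluster_a = a, cluster_b = b,
      gene = colnames(m)[ok],
      direction = unname(dir[ok]),
      p = unname(pv[ok]),
      p_adj = p.adjust(pv[ok], method = "BH")
    )
  }
  res <- bind_rows(out)
  attr(res, "alpha") <- alpha
  class(res) <- c("mgpop_de", class(res))
  res
}

# Orient a DE table relative to one cluster: direction > 0 means up in
# `cluster`.
orient_de <- function(de, cluster) {
  de <- filter(de, .data$cluster_a == cluster | .data$cluster_b == cluster)
  mutate(de,
         other = ifelse(.data$cluster_a == cluster, .data$cluster_b,
                        .data$cluster_a),
         direction = ifelse(.data$cluster_a == cluster, .data$direction,
                            -.data$direction))
}

#' Rank cluster-defining genes
#'
#' For one cluster, counts per gene the number of pairwise comparisons in
#' which it is significantly upregulated (adjusted p below `alpha`), removes
#' any gene significantly downregulated against any other cluster, and
#' ranks the remainder by up-count (descending), then by the best adjusted p
#' among the up-comparisons, then by gene id.
#'
#' @param de result of [pairwise_de()].
#' @param cluster cluster id.
#' @param alpha adjusted-p significance level (defaults to the level stored
#'   in `de`).
#' @return tibble with `gene`, `up_count`, `best_p_adj`, `rank`.
#' @export
rank_cluster_genes <- function(de, cluster, alpha = attr(de, "alpha") %||% 0.05) {
  o <- orient_de(de, cluster)
  sig <- filter(o, .data$p_adj < alpha)
  down_genes <- unique(sig$gene[sig$direction < 0])
  up <- filter(sig, .data$direction > 0, !(.data$gene %in% down_genes))
  if (!nrow(up)) {
    return(tibble(gene = character(), up_count = integer(),
                  best_p_adj = double(), rank = integer()))
  }
  up |>
    group_by(.data$gene) |>
    summarise(up_count = n(), best_p_adj = min(.data$p_adj),
              .groups = "drop") |>
    arrange(desc(.data$up_count), .data$best_p_adj, .data$gene) |>
    mutate(rank = seq_len(n()))
}

#' Top-N signature gene set
#'
#' First `n` genes of a [rank_cluster_genes()] ranking; warns when fewer are
#' available.
#'
#' @param ranked tibble from [rank_cluster_genes()].
#' @param n number of genes requested.
#' @return character vector of gene ids (possibly shorter than `n`).
#' @export
signature_top_n <- function(ranked, n = 50) {
  if (n == 0) return(character(0))
  if (nrow(ranked) < n) {
    warning("only ", nrow(ranked), " eligible genes for top-", n, " signature")
  }
  head(ranked$gene, n)
}

#' Cluster signatures for all clusters
#'
#' Convenience wrapper running [rank_cluster_genes()] for every cluster and
#' returning both the full constrained gene lists (used for enrichment) and
#' the top-N sets.
#'
#' @param de result of [pairwise_de()].
#' @param alpha adjusted-p significance level.
#' @param top_n signature size.
#' @return list with `ranked` (named list of ranking tibbles), `full`
#'   (named list of all constrained genes) and `top` (named list of top-N
#'   sets).
#' @export
cluster_signatures <- function(de, alpha = attr(de, "alpha") %||% 0.05,
                               top_n = 50) {
  clusters <- sort(unique(c(de$cluster_a, de$cluster_b)))
  ranked <- lapply(clusters, function(cl) rank_cluster_genes(de, cl, alpha))
  names(ranked) <- paste0("cluster_", clusters)
  list(
    ranked = ranked,
    full = lapply(ranked, function(r) r$gene),
    top = lapply(ranked, function(r) suppressWarnings(signature_top_n(r, top_n)))
  )
}

#' Dot-plot summary statistics
#'
#' For each (gene, cluster): the fraction of the cluster's cells in which
#' the gene is detected (CPM > 0, equivalently count > 0) and the mean
#' z-score, where the z-score is computed per gene over all cells and then
#' averaged within each cluster. Genes with zero variance have z-score 0
#' everywhere.
#'
#' @param expr cells x genes log-CPM expression matrix.
#' @param labels integer cluster labels.
#' @param genes genes to summarise.
#' @return tibble with `gene`, `cluster`, `frac_detected`, `mean_z`.
#' @export
dotplot_stats <- function(expr, labels, genes) {
  stopifnot(all(genes %in% colnames(expr)))
  labels <- as.integer(labels)
  z <- zscore_genes(expr, genes)
  detected <- as.matrix(expr)[, genes, drop = FALSE] > 0
  clusters <- sort(unique(labels))
  out <- list()
  for (cl in clusters) {
    in_cl <- labels == cl
    out[[length(out) + 1]] <- tibble(
      gene = genes, cluster = cl,
      frac_detected = unname(colMeans(detected[in_cl, , drop = FALSE])),
      mean_z = unname(colMeans(z[in_cl, , drop = FALSE]))
    )
  }
  bind_rows(out)
}

#' Dot plot of marker detection and expression
#'
#' @param stats tibble from [dotplot_stats()].
#' @return a ggplot object: genes in rows, clusters in columns, dot size =
#'   fraction detected, colour = mean z-score.
#' @export
plot_dotplot <- function(stats) {
  ggplot2::ggplot(stats, ggplot2::aes(
    x = factor(.data$cluster), y = .data$gene,
    size = .data$frac_detected, colour = .data$mean_z
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_size_area(max_size = 6, limits = c(0, 1)) +
    ggplot2::scale_colour_gradient2(low = "navy", mid = "grey90",
                                    high = "firebrick") +
    ggplot2::labs(x = "cluster", y = NULL, size = "fraction detected",
                  colour = "mean z-score") +
    ggplot2::theme_minimal()
}
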