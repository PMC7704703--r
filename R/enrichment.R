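# Hypergeometric gene-set enrichment, directional trait overlap, and the
# per-cell module-association statistic.

#' Upper-tail hypergeometric test
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' observing at least `k` annotated genes in a draw of `n` from a universe
#' of `N` genes of which `K` are annotated. Vectorized over its arguments;
#' evaluated through the stable tail implementation of [stats::phyper()].
#'
#' @param universe_size total genes `N`.
#' @param annotated annotated genes `K`.
#' @param drawn query size `n`.
#' @param overlap observed overlap `k`.
#' @return p-value(s) in `(0, 1]`.
#' @export
#' @examples
#' hypergeometric_test(10, 5, 5, 5)  # 1 / choose(10, 5)
hypergeometric_test <- function(universe_size, annotated, drawn, overlap) {
  stopifnot(
    all(annotated <= universe_size), all(drawn <= universe_size),
    all(overlap <= pmin(annotated, drawn)), all(overlap >= 0)
  )
  phyper(overlap - 1, annotated, universe_size - annotated, drawn,
         lower.tail = FALSE)
}

#' Gene-set enrichment of a query set against a collection
#'
#' One upper-tail hypergeometric test per annotation set, with multiple-
#' testing correction across the collection. Query and annotation genes
#' outside the universe are dropped (with a message when the query loses
#' genes).
#'
#' @param query character vector of query genes (e.g. a cluster signature).
#' @param collection named list of annotation gene sets.
#' @param universe character vector of universe genes.
#' @param correction `"BH"` or `"bonferroni"`.
#' @return tibble with `set`, `universe_size`, `set_size`, `query_size`,
#'   `overlap`, `p`, `p_adj`, and `overlap_genes` (list column), sorted by
#'   `p`.
#' @export
enrich_sets <- function(query, collection, universe,
                        correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  if (!length(collection)) stop("empty annotation collection")
  universe <- unique(universe)
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    message(length(dropped), " query gene(s) outside the universe dropped")
  }
  query <- intersect(unique(query), universe)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(unique(collection[[nm]]), universe)
    ov <- intersect(query, members)
    n_set <- length(members)
    n_query <- length(query)
    n_ov <- length(ov)
    tibble(
      set = nm,
      universe_size = length(universe),
      set_size = n_set,
      query_size = n_query,
      overlap = n_ov,
      p = hypergeometric_test(length(universe), n_set, n_query, n_ov),
      overlap_genes = list(ov)
    )
  })
  out <- bind_rows(rows)
  out$p_adj <- p.adjust(out$p, method = correction)
  arrange(select(out, "set", "universe_size", "set_size", "query_size",
                 "overlap", "p", "p_adj", "overlap_genes"), .data$p)
}

#' Directional trait-association overlap
#'
#' For each (cluster signature, trait) combination, tests the overlap of the
#' cluster's upregulated genes with the trait's positively and negatively
#' associated gene lists using the upper-tail hypergeometric test, adjusts
#' across all tests, and reports a signed `-log10` adjusted p whose sign is
#' the direction with the smaller adjusted p (positive = overlap with the
#' trait-upregulated list). Both directions are retained.
#'
#' @param signatures named list of per-cluster gene sets.
#' @param traits tibble with columns `trait`, `gene`, `sign` (+1/-1).
#' @param universe character vector of universe genes.
#' @param correction `"BH"` or `"bonferroni"`.
#' @return tibble with `cluster`, `trait`, per-direction overlap and
#'   adjusted p (`overlap_up`, `p_adj_up`, `overlap_down`, `p_adj_down`),
#'   `signed_log10_p_adj` and `direction` (`"up"`/`"down"`).
#' @export
directional_trait_overlap <- function(signatures, traits, universe,
                                      correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  stopifnot(all(c("trait", "gene", "sign") %in% names(traits)))
  if (!nrow(traits)) stop("empty trait list")
  if (any(!traits$sign %in% c(-1, 1))) stop("trait sign must be +1 or -1")
  universe <- unique(universe)
  trait_names <- unique(traits$trait)
  rows <- list()
  for (cl in names(signatures)) {
    sig <- intersect(unique(signatures[[cl]]), universe)
    for (tr in trait_names) {
      for (sgn in c(1, -1)) {
        genes <- traits$gene[traits$trait == tr & traits$sign == sgn]
        if (!length(genes)) stop("trait ", tr, " lacks a sign ", sgn, " list")
        set <- intersect(unique(genes), universe)
        ov <- length(intersect(sig, set))
        rows[[length(rows) + 1]] <- tibble(
          cluster = cl, trait = tr, sign = sgn, overlap = ov,
          p = hypergeometric_test(length(universe), length(set),
                                  length(sig), ov)
        )
      }
    }
  }
  long <- bind_rows(rows)
  long$p_adj <- p.adjust(long$p, method = correction)
  wide <- long |>
    tidyr::pivot_wider(
      id_cols = c("cluster", "trait"),
      names_from = "sign",
      values_from = c("overlap", "p_adj"),
      names_glue = "{.value}_{ifelse(sign == 1, 'up', 'down')}"
    )
  wide |>
    mutate(
      direction = ifelse(.data$p_adj_up <= .data$p_adj_down, "up", "down"),
      signed_log10_p_adj = ifelse(
        .data$direction == "up",
        -log10(.data$p_adj_up),
        log10(.data$p_adj_down)
      )
    )
}

#' Per-cell module association of clusters
#'
#' For each cell, an upper-tail hypergeometric p-value for the overlap
#' between the genes detected in that cell (count > 0) and a module's
#' genes, with the matrix's gene set as universe. Per cluster, the
#' distribution of log p-values is compared against the constant
#' `log(0.01)` with a rank test, and p-values are Bonferroni-corrected over
#' clusters x modules.
#'
#' The reference comparison of a sample against a constant is formally a
#' one-sample setting; the default mode is the Wilcoxon signed-rank test
#' against `log(0.01)`, with a two-sample mode (Mann-Whitney against a
#' degenerate pseudo-sample at the constant) available.
#'
#' @param counts cells x genes count matrix.
#' @param labels integer cluster labels.
#' @param modules named list of module gene sets.
#' @param mode `"signed_rank"` (one-sample, default) or `"two_sample"`.
#' @return tibble with `cluster`, `module`, `n_cells`, `median_log_p`,
#'   `p`, `p_adj`.
#' @export
per_cell_module_association <- function(counts, labels, modules,
                                        mode = c("signed_rank",
                                                 "two_sample")) {
  mode <- match.arg(mode)
  if (!length(modules)) stop("no modules supplied")
  if (any(lengths(modules) == 0)) stop("empty module(s)")
  labels <- as.integer(labels)
  universe <- colnames(counts)
  n_universe <- length(universe)
  detected <- counts > 0
  n_detected <- Matrix::rowSums(detected)
  clusters <- sort(unique(labels))
  rows <- list()
  for (md in names(modules)) {
    mod <- intersect(unique(modules[[md]]), universe)
    if (!length(mod)) stop("module ", md, " has no genes in the universe")
    ov <- Matrix::rowSums(detected[, mod, drop = FALSE])
    log_p <- log(hypergeometric_test(n_universe, length(mod),
                                     n_detected, ov))
    for (cl in clusters) {
      lp <- log_p[labels == cl]
      ref <- log(0.01)
      test <- if (mode == "signed_rank") {
        if (all(lp == ref)) list(p.value = 1) else
          suppressWarnings(wilcox.test(lp, mu = ref))
      } else {
        suppressWarnings(wilcox.test(lp, rep(ref, length(lp))))
      }
      rows[[length(rows) + 1]] <- tibble(
        cluster = cl, module = md, n_cells = length(lp),
        median_log_p = median(lp), p = test$p.value
      )
    }
  }
  out <- bind_rows(rows)
  out$p_adj <- p.adjust(out$p, method = "bonferroni")
  out
}
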