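# Cross-dataset label transfer: CCA joint embedding, Gaussian Naive Bayes
# classification, annotation-transfer enrichment, and donor-level
# cluster-proportion testing.

standardize_genes <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
}

#' Joint embedding of two datasets via canonical correlation analysis
#'
#' Both expression matrices are gene-standardized over the shared gene set,
#' and the singular value decomposition of their cross-product
#' `K = X_ref %*% t(X_query)` yields paired canonical vectors. All cells
#' (including cells outside the optional SVD basis subsample) are embedded
#' through the gene-loading projections `X %*% (t(X_other_basis) %*% V)`,
#' which places basis cells at `U %*% D` and `V %*% D` — the two datasets'
#' coordinates share the same per-component scale. Coordinates are then
#' L2-normalized per cell, which removes global magnitude (platform)
#' differences.
#'
#' @param ref_expr,query_expr cells x genes expression matrices (log-CPM or
#'   residuals).
#' @param shared_genes genes used for the embedding (e.g. the union of both
#'   datasets' variable genes intersected with the shared genes).
#' @param n_cc number of canonical components (reduced with a warning when
#'   it exceeds the usable rank).
#' @param n_basis optional number of cells per dataset used for the SVD
#'   basis (default: all cells); the embedding is still computed for every
#'   cell.
#' @param seed seed for the basis subsample.
#' @return object of class `mgpop_cca`: list with `ref` and `query`
#'   embedding matrices (cells x n_cc, L2-normalized rows), `d` singular
#'   values and `canonical_cor` (per-component correlation of the two gene
#'   loading vectors).
#' @export
cca_integrate <- function(ref_expr, query_expr, shared_genes,
                          n_cc = 20, n_basis = NULL, seed = 1L) {
  shared_genes <- intersect(intersect(shared_genes, colnames(ref_expr)),
                            colnames(query_expr))
  if (length(shared_genes) < 2) stop("fewer than 2 usable shared genes")
  if (n_cc > length(shared_genes)) {
    warning("n_cc reduced to ", length(shared_genes), " (shared genes)")
    n_cc <- length(shared_genes)
  }
  xr <- standardize_genes(ref_expr[, shared_genes, drop = FALSE])
  xq <- standardize_genes(query_expr[, shared_genes, drop = FALSE])
  set.seed(as.integer(seed))
  br <- if (!is.null(n_basis) && n_basis < nrow(xr)) {
    sort(sample.int(nrow(xr), n_basis))
  } else seq_len(nrow(xr))
  bq <- if (!is.null(n_basis) && n_basis < nrow(xq)) {
    sort(sample.int(nrow(xq), n_basis))
  } else seq_len(nrow(xq))
  rank_cap <- min(length(br), length(bq), length(shared_genes))
  if (n_cc > rank_cap) {
    warning("n_cc reduced to ", rank_cap)
    n_cc <- rank_cap
  }
  k <- xr[br, , drop = FALSE] %*% t(xq[bq, , drop = FALSE])
  sv <- svd(k, nu = n_cc, nv = n_cc)
  load_r <- t(xr[br, , drop = FALSE]) %*% sv$u    # genes x n_cc
  load_q <- t(xq[bq, , drop = FALSE]) %*% sv$v
  emb_r <- xr %*% load_q                           # = U D on the basis
  emb_q <- xq %*% load_r                           # = V D on the basis
  l2 <- function(m) {
    nrm <- sqrt(rowSums(m^2))
    nrm[nrm == 0] <- 1
    m / nrm
  }
  cc_cor <- vapply(seq_len(n_cc), function(j) {
    stats::cor(load_r[, j], load_q[, j])
  }, 0)
  structure(
    list(ref = l2(emb_r), query = l2(emb_q),
         d = sv$d[seq_len(n_cc)], canonical_cor = cc_cor,
         genes = shared_genes),
    class = "mgpop_cca"
  )
}

#' @export
print.mgpop_cca <- function(x, ...) {
  cat(sprintf("<mgpop_cca> %d + %d cells, %d components, %d genes\n",
              nrow(x$ref), nrow(x$query), ncol(x$ref), length(x$genes)))
  invisible(x)
}

#' Classify query cells with a Gaussian Naive Bayes model
#'
#' Fits, per reference cluster, an independent Gaussian model on the
#' reference canonical coordinates (class variances floored at `var_floor`
#' so tiny classes cannot degenerate) and assigns each query cell to the
#' class with the largest posterior.
#'
#' @param embedding an `mgpop_cca` from [cca_integrate()], or a list with
#'   `ref` and `query` coordinate matrices.
#' @param ref_labels reference cluster labels.
#' @param prior class prior: `"uniform"` or `"proportional"` to reference
#'   cluster sizes.
#' @param var_floor minimum per-class per-dimension variance.
#' @return tibble with `cell_id`, `assigned_cluster`, `max_posterior`, and
#'   one `posterior_<cluster>` column per class.
#' @export
nb_classify <- function(embedding, ref_labels,
                        prior = c("proportional", "uniform"),
                        var_floor = 1e-6) {
  prior <- match.arg(prior)
  ref <- embedding$ref
  query <- embedding$query
  stopifnot(nrow(ref) == length(ref_labels))
  ref_labels <- as.integer(ref_labels)
  clusters <- sort(unique(ref_labels))
  log_prior <- if (prior == "uniform") {
    setNames(rep(-log(length(clusters)), length(clusters)), clusters)
  } else {
    tab <- table(factor(ref_labels, levels = clusters))
    setNames(log(as.numeric(tab) / sum(tab)), clusters)
  }
  log_post <- vapply(clusters, function(cl) {
    m <- ref[ref_labels == cl, , drop = FALSE]
    mu <- colMeans(m)
    v <- pmax(apply(m, 2, var), var_floor)
    v[is.na(v)] <- var_floor                       # single-cell class
    ll <- -0.5 * colSums((t(query) - mu)^2 / v) -
      0.5 * sum(log(2 * pi * v))
    ll + log_prior[[as.character(cl)]]
  }, numeric(nrow(query)))
  # normalized posteriors per cell
  mx <- apply(log_post, 1, max)
  post <- exp(log_post - mx)
  post <- post / rowSums(post)
  colnames(post) <- paste0("posterior_", clusters)
  assigned <- clusters[max.col(post, ties.method = "first")]
  out <- tibble(
    cell_id = rownames(query) %||% as.character(seq_len(nrow(query))),
    assigned_cluster = assigned,
    max_posterior = post[cbind(seq_len(nrow(post)),
                               max.col(post, ties.method = "first"))]
  )
  dplyr::bind_cols(out, as_tibble(post))
}

#' Enrichment of query annotations within reference clusters
#'
#' For each (query annotation, assigned reference cluster) combination, an
#' upper-tail hypergeometric test: universe = all query cells, annotated =
#' cells carrying the annotation, drawn = cells assigned to the cluster,
#' overlap = annotated cells assigned to the cluster; Bonferroni correction
#' over all combinations.
#'
#' @param annotations per-query-cell annotation labels (e.g. the source
#'   study's cluster names).
#' @param assigned per-query-cell assigned reference cluster.
#' @return tibble with `annotation`, `cluster`, `n_annotation`,
#'   `n_cluster`, `overlap`, `p`, `p_adj`.
#' @export
transfer_enrichment <- function(annotations, assigned) {
  stopifnot(length(annotations) == length(assigned))
  if (!length(annotations) || all(is.na(annotations))) {
    stop("empty annotation vector")
  }
  n <- length(annotations)
  rows <- list()
  for (ann in sort(unique(annotations))) {
    in_ann <- annotations == ann
    if (!any(in_ann)) stop("empty annotation: ", ann)
    for (cl in sort(unique(assigned))) {
      in_cl <- assigned == cl
      rows[[length(rows) + 1]] <- tibble(
        annotation = ann, cluster = cl,
        n_annotation = sum(in_ann), n_cluster = sum(in_cl),
        overlap = sum(in_ann & in_cl),
        p = hypergeometric_test(n, sum(in_ann), sum(in_cl),
                                sum(in_ann & in_cl))
      )
    }
  }
  out <- bind_rows(rows)
  out$p_adj <- p.adjust(out$p, method = "bonferroni")
  out
}

#' Donor-level cluster proportion table
#'
#' Per donor, the proportion of cells in each cluster (rows sum to 1),
#' joined with donor covariates.
#'
#' @param meta per-cell metadata with `cell_id`, `donor`, `group`, `age`,
#'   `sex`.
#' @param labels per-cell cluster labels aligned with `meta` rows.
#' @return tibble with one row per donor x cluster: `donor`, `cluster`,
#'   `n_cells`, `proportion`, `group`, `age`, `sex`.
#' @export
proportion_table <- function(meta, labels) {
  stopifnot(nrow(meta) == length(labels))
  clusters <- sort(unique(as.integer(labels)))
  tab <- meta |>
    mutate(cluster = as.integer(labels)) |>
    group_by(.data$donor) |>
    mutate(donor_total = n()) |>
    ungroup() |>
    group_by(.data$donor, .data$cluster, .data$group, .data$age, .data$sex,
             .data$donor_total) |>
    summarise(n_cells = n(), .groups = "drop")
  donors <- dplyr::distinct(tab, .data$donor, .data$group, .data$age,
                            .data$sex, .data$donor_total)
  grid <- tidyr::crossing(donors, cluster = clusters)
  tab <- grid |>
    left_join(select(tab, "donor", "cluster", "n_cells"),
              by = c("donor", "cluster")) |>
    mutate(n_cells = tidyr::replace_na(.data$n_cells, 0L))
  tab |>
    mutate(proportion = .data$n_cells / .data$donor_total) |>
    select("donor", "cluster", "n_cells", "proportion", "group", "age",
           "sex") |>
    arrange(.data$donor, .data$cluster)
}

#' Covariate-adjusted group test of cluster proportions
#'
#' Per cluster, ordinary least squares of the per-donor proportion on a
#' group indicator plus age and sex; two-sided t-test on the group
#' coefficient with Bonferroni correction across the clusters tested. The
#' donor is the unit of analysis.
#'
#' @param table tibble from [proportion_table()].
#' @param case_group the group level coded 1 (default: alphabetically
#'   first of the two levels is the reference).
#' @param clusters clusters to test (default: all).
#' @return tibble with `cluster`, `coefficient`, `conf_low`, `conf_high`,
#'   `p`, `p_adj`.
#' @export
proportion_group_model <- function(table, case_group = NULL,
                                   clusters = sort(unique(table$cluster))) {
  groups <- sort(unique(table$group))
  if (length(groups) < 2) stop("need at least two donor groups")
  case_group <- case_group %||% groups[length(groups)]
  rows <- lapply(clusters, function(cl) {
    d <- filter(table, .data$cluster == cl)
    d$is_case <- as.integer(d$group == case_group)
    fit <- lm(proportion ~ is_case + age + sex, data = d)
    ci <- confint(fit, "is_case", level = 0.95)
    tibble(
      cluster = cl,
      coefficient = unname(coef(fit)["is_case"]),
      conf_low = ci[1], conf_high = ci[2],
      p = summary(fit)$coefficients["is_case", "Pr(>|t|)"]
    )
  })
  out <- bind_rows(rows)
  out$p_adj <- pmin(1, out$p * length(clusters))
  out
}

#' Non-parametric group test of cluster proportions
#'
#' Per cluster, a rank test of per-donor proportions between groups:
#' Mann-Whitney (default, two groups) or Kruskal-Wallis (any number of
#' groups; with two groups the tests agree up to continuity handling), with
#' Benjamini-Hochberg correction across clusters. Groups with a single
#' donor trigger a low-power warning.
#'
#' @param table tibble from [proportion_table()].
#' @param clusters clusters to test (default: all).
#' @param method `"mann_whitney"` or `"kruskal"`.
#' @param alpha significance level for the `significant` flag.
#' @return tibble with `cluster`, `p`, `p_adj`, `significant`.
#' @export
proportion_nonparametric_test <- function(table,
                                          clusters = sort(unique(table$cluster)),
                                          method = c("mann_whitney",
                                                     "kruskal"),
                                          alpha = 0.05) {
  method <- match.arg(method)
  groups <- sort(unique(table$group))
  if (method == "mann_whitney" && length(groups) != 2) {
    stop("mann_whitney requires exactly two groups")
  }
  n_donors <- table |>
    dplyr::distinct(.data$donor, .data$group) |>
    dplyr::count(.data$group)
  if (any(n_donors$n < 2)) {
    warning("group(s) with a single donor: low power")
  }
  rows <- lapply(clusters, function(cl) {
    d <- filter(table, .data$cluster == cl)
    p <- if (method == "mann_whitney") {
      suppressWarnings(
        wilcox.test(proportion ~ group, data = d)$p.value
      )
    } else {
      kruskal.test(proportion ~ group, data = d)$p.value
    }
    tibble(cluster = cl, p = p)
  })
  out <- bind_rows(rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out
}

#' Forest plot of proportion-model coefficients
#'
#' @param model tibble from [proportion_group_model()].
#' @param alpha significance level for highlighting.
#' @return a ggplot object.
#' @export
plot_proportion_forest <- function(model, alpha = 0.05) {
  model <- mutate(model, significant = .data$p_adj < alpha)
  ggplot2::ggplot(model, ggplot2::aes(
    x = .data$coefficient, y = factor(.data$cluster),
    colour = .data$significant
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.2
    ) +
    ggplot2::labs(x = "group coefficient (case - control)", y = "cluster",
                  colour = paste0("adjusted p < ", alpha)) +
    ggplot2::theme_minimal()
}
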