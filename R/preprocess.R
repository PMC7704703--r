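#' QC-filter cells by total UMI
#'
#' Keeps exactly the cells whose total UMI count is strictly greater than
#' `min_umi` and strictly less than `max_umi` (both bounds exclusive). The
#' gene set is unchanged.
#'
#' @param counts cells x genes count matrix.
#' @param min_umi,max_umi exclusive bounds on per-cell total UMI.
#' @return the filtered count matrix.
#' @export
#' @examples
#' m <- Matrix::Matrix(diag(c(1001, 500)), sparse = TRUE)
#' dimnames(m) <- list(c("a", "b"), c("g1", "g2"))
#' rownames(filter_cells(m))
filter_cells <- function(counts, min_umi = 1000, max_umi = 10000) {
  totals <- Matrix::rowSums(counts)
  keep <- totals > min_umi & totals < max_umi
  if (!any(keep)) {
    stop(sprintf("no cells with total UMI in (%s, %s)", min_umi, max_umi))
  }
  counts[keep, , drop = FALSE]
}

#' Drop genes detected in too few cells
#'
#' Genes detected (count > 0) in fewer than `min_cells` cells are removed
#' before normalization; near-absent genes cannot support stable variance or
#' differential-expression estimates.
#'
#' @param counts cells x genes count matrix.
#' @param min_cells minimum number of cells a gene must be detected in.
#' @return the filtered count matrix; dropped genes are reported via message.
#' @export
filter_genes <- function(counts, min_cells = 3) {
  detected <- Matrix::colSums(counts > 0)
  keep <- detected >= min_cells
  if (!any(keep)) stop("no genes detected in >= ", min_cells, " cells")
  if (any(!keep)) {
    message(sum(!keep), " gene(s) detected in < ", min_cells, " cells dropped")
  }
  counts[, keep, drop = FALSE]
}

expr_state <- function(x) attr(x, "mg_state")

set_state <- function(x, state) {
  attr(x, "mg_state") <- state
  x
}

#' Normalize counts to log2(CPM + 1)
#'
#' Per cell, each count becomes `log2(1e6 * count / total + 1)`. For UMI data
#' counts-per-million and transcripts-per-million coincide (no gene-length
#' normalization applies).
#'
#' @param counts cells x genes count matrix.
#' @return dense cells x genes matrix tagged with state `"cpm_log"`.
#' @export
normalize_cpm_log <- function(counts) {
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0)) stop("cell(s) with zero total counts")
  x <- as.matrix(counts)
  x <- log2(sweep(x, 1, 1e6 / totals, "*") + 1)
  set_state(x, "cpm_log")
}

#' Regress batch identity and total UMI out of normalized expression
#'
#' Per gene, ordinary least squares of expression on batch indicator dummies
#' plus per-cell total UMI; the output is the residual plus the gene's grand
#' mean, so per-gene means are preserved and downstream PCA centering stays
#' explicit. Batches with a single cell cannot support their own indicator
#' and are folded into the reference level with a warning.
#'
#' @param expr cells x genes matrix of log-normalized expression.
#' @param batch per-cell batch labels.
#' @param total_umi per-cell total UMI counts.
#' @return dense matrix tagged with state `"residual"`.
#' @export
regress_covariates <- function(expr, batch, total_umi) {
  stopifnot(length(batch) == nrow(expr), length(total_umi) == nrow(expr))
  batch <- as.character(batch)
  sizes <- table(batch)
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons)) {
    warning("batch(es) with a single cell folded into the reference level: ",
            paste(singletons, collapse = ", "))
    batch[batch %in% singletons] <- names(sizes)[which.max(sizes)]
  }
  batch <- factor(batch)
  design <- if (nlevels(batch) > 1) {
    model.matrix(~ batch + total_umi)
  } else {
    model.matrix(~total_umi)
  }
  expr <- as.matrix(expr)
  fit <- stats::lm.fit(design, expr)       # rank-deficiency safe
  res <- fit$residuals
  res <- sweep(res, 2, colMeans(expr), "+")
  dimnames(res) <- dimnames(expr)
  set_state(res, "residual")
}

#' Select variable genes (variance greater than mean)
#'
#' Returns the genes whose variance across cells strictly exceeds their
#' mean, in input gene order. Ties (variance equal to mean) are excluded.
#' The criterion is a Poisson-reference overdispersion screen and is meant
#' to be applied on the count scale (the pipeline applies it to the
#' QC-filtered UMI counts): under pure sampling noise variance equals the
#' mean, so genes exceeding it carry structure. Applying it to
#' log-transformed values would instead exclude the high-expression genes
#' that carry most of the cluster signal.
#'
#' @param counts cells x genes matrix (UMI counts in the intended use; the
#'   statistic is computed on whatever scale is supplied).
#' @return character vector of gene identifiers.
#' @export
select_variable_genes <- function(counts) {
  if (nrow(counts) < 2) stop("need at least 2 cells to estimate variance")
  counts <- as.matrix(counts)
  mu <- colMeans(counts)
  v <- colSums(counts^2)
  v <- (v - nrow(counts) * mu^2) / (nrow(counts) - 1)
  colnames(counts)[v > mu]
}

#' Z-score genes across all cells
#'
#' Per gene, `(x - mean) / SD` over all cells using the sample SD
#' (denominator n - 1). Genes with zero SD map to all zeros.
#'
#' @param expr cells x genes expression matrix.
#' @param genes optional gene subset (default: all genes).
#' @return dense matrix tagged with state `"zscored"`.
#' @export
zscore_genes <- function(expr, genes = colnames(expr)) {
  x <- as.matrix(expr)[, genes, drop = FALSE]
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  z <- sweep(x, 2, mu, "-")
  nz <- sdv > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sdv[nz], "/")
  z[, !nz] <- 0
  set_state(z, "zscored")
}

#' Run the pre-clustering transformations in order
#'
#' Convenience wrapper: cell QC, gene detection filter, log-CPM
#' normalization, and regression of batch identity and sequencing depth.
#' Depth enters the regression as log total UMI: log-normalized expression
#' depends on depth mostly through dropout, a relationship far closer to
#' linear in log depth than in raw depth, and the raw-scale covariate leaves
#' classifiable depth structure behind.
#'
#' @param counts cells x genes count matrix.
#' @param meta per-cell metadata tibble with `cell_id` and `batch` columns,
#'   aligned by `cell_id`.
#' @param config a [pipeline_config()].
#' @return list of class `mgpop_prep` with `residual` (state-tagged
#'   matrix), `counts` (the QC-filtered counts) and `meta` (filtered
#'   metadata).
#' @export
preprocess <- function(counts, meta, config = pipeline_config()) {
  validate_count_matrix(counts)
  counts <- filter_cells(counts, config$min_umi, config$max_umi)
  counts <- filter_genes(counts)
  meta <- meta[match(rownames(counts), meta$cell_id), , drop = FALSE]
  expr <- normalize_cpm_log(counts)
  res <- regress_covariates(expr, meta$batch, log(Matrix::rowSums(counts)))
  structure(
    list(residual = res, counts = counts, meta = as_tibble(meta)),
    class = "mgpop_prep"
  )
}
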