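#' Validate a cells-by-genes UMI count matrix
#'
#' Checks the container invariants required throughout the pipeline:
#' non-negative integer counts, unique non-empty cell and gene identifiers,
#' and identifier lists matching the matrix dimensions.
#'
#' @param counts matrix or [Matrix::sparseMatrix()] with cells in rows and
#'   genes in columns; `dimnames` carry the cell and gene identifiers.
#' @return `counts`, invisibly, if valid; otherwise an error.
#' @export
validate_count_matrix <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must carry cell (row) and gene (column) identifiers")
  }
  if (anyDuplicated(rownames(counts))) stop("cell identifiers are not unique")
  if (anyDuplicated(colnames(counts))) stop("gene identifiers are not unique")
  vals <- if (inherits(counts, "sparseMatrix")) counts@x else as.vector(counts)
  if (length(vals) && min(vals) < 0) stop("count matrix has negative entries")
  if (length(vals) && any(vals != round(vals))) {
    stop("count matrix has non-integer entries")
  }
  invisible(counts)
}

#' Read a 10x-style count matrix directory
#'
#' Expects a Matrix Market coordinate file plus single-column barcode and
#' feature identifier files (no headers), the layout used by 10x Genomics
#' CellRanger output. On disk the matrix is genes x cells; the returned
#' matrix is normalised to cells x genes.
#'
#' @param path directory containing the three files.
#' @param matrix_file,barcodes_file,features_file file names within `path`.
#' @return sparse cells x genes count matrix with cell/gene dimnames.
#' @export
read_count_matrix <- function(path,
                              matrix_file = "matrix.mtx",
                              barcodes_file = "barcodes.tsv",
                              features_file = "features.tsv") {
  paths <- file.path(path, c(matrix_file, barcodes_file, features_file))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  m <- Matrix::readMM(paths[1])
  barcodes <- readLines(paths[2])
  features <- readLines(paths[3])
  if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)                      # stored genes x cells (10x layout)
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(features))) {
    stop(sprintf(
      "matrix dimensions (%d x %d) match neither features x barcodes (%d x %d) nor barcodes x features",
      nrow(m), ncol(m), length(features), length(barcodes)
    ))
  }
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(barcodes, features)
  validate_count_matrix(m)
  m
}

#' Write a count matrix as a 10x-style directory
#'
#' Inverse of [read_count_matrix()]: writes the Matrix Market triplet file in
#' genes x cells orientation plus barcode and feature lists.
#'
#' @inheritParams read_count_matrix
#' @param counts cells x genes count matrix with dimnames.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path,
                               matrix_file = "matrix.mtx",
                               barcodes_file = "barcodes.tsv",
                               features_file = "features.tsv") {
  validate_count_matrix(counts)
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  m <- Matrix::t(methods::as(methods::as(counts, "dMatrix"), "CsparseMatrix"))
  Matrix::writeMM(m, file.path(path, matrix_file))
  writeLines(rownames(counts), file.path(path, barcodes_file))
  writeLines(colnames(counts), file.path(path, features_file))
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated GMT dialect: set name, description, then member genes.
#' Duplicate members within a set are dropped; duplicate set names or lines
#' with fewer than three fields are errors.
#'
#' @param path GMT file path.
#' @return named list of character vectors (empty list for an empty file);
#'   descriptions kept in the `"descriptions"` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(structure(list(), descriptions = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stop("GMT line(s) with fewer than 3 fields: line ", paste(short, collapse = ", "))
  }
  nms <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  structure(sets, descriptions = setNames(vapply(fields, `[[`, "", 2), nms))
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param descriptions optional per-set description (defaults to the set name).
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets))
  if (!length(sets)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("all gene sets must be named")
  }
  if (any(lengths(sets) == 0)) stop("empty gene set(s) cannot be written")
  desc <- descriptions %||% attr(sets, "descriptions") %||%
    setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as CSV with a provenance header
#'
#' Writes a tibble/data frame as UTF-8 CSV preceded by a comment line
#' recording the configuration hash and seed, so every stochastic result can
#' be traced to the run that produced it. Row order is made deterministic by
#' sorting on `sort_by` (all columns by default).
#'
#' @param table data frame with unique column names.
#' @param path output CSV path.
#' @param sort_by character vector of columns defining the row order.
#' @param config optional `mgpop_config` for the provenance line.
#' @param seed optional seed recorded in the provenance line.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(table, path, sort_by = names(table),
                                config = NULL, seed = NULL) {
  if (anyDuplicated(names(table))) stop("table column names must be unique")
  if (length(sort_by)) {
    table <- dplyr::arrange(as.data.frame(table),
                            dplyr::across(dplyr::all_of(sort_by)))
  }
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  hash <- if (!is.null(config)) config_hash(config) else "none"
  writeLines(sprintf("# mgpop config_hash=%s seed=%s", hash,
                     seed %||% "none"), con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results_table()]
#'
#' @param path CSV path.
#' @return tibble; the provenance line is exposed as attribute
#'   `"provenance"`.
#' @export
read_results_table <- function(path) {
  first <- readLines(path, n = 1)
  tbl <- as_tibble(utils::read.csv(path, comment.char = "#",
                                   stringsAsFactors = FALSE))
  if (startsWith(first, "#")) attr(tbl, "provenance") <- sub("^#\\s*", "", first)
  tbl
}
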