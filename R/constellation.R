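# Inter-cluster relatedness via repeated pairwise cross-validated
# classification: the constellation analysis.

#' Per-cell classification consistency for a cluster pair
#'
#' Restricts to the two clusters' cells and, for each of `n_reps`
#' repetitions, runs stratified 4-fold cross-validation with a random-forest
#' classifier (each cell predicted exactly once per repetition by a forest
#' trained on the other 75 percent). The returned count is, per cell, the
#' number of repetitions in which the prediction matched the cell's own
#' cluster.
#'
#' @param features cells x d matrix of PC coordinates (parent partition's
#'   space).
#' @param labels integer cluster labels aligned with `features` rows.
#' @param pair length-2 vector of cluster ids.
#' @param n_reps number of repetitions.
#' @param train_frac training fraction; folds are `round(1 / (1 -
#'   train_frac))` (0.75 gives 4-fold cross-validation).
#' @param seed integer seed.
#' @param num_trees trees per forest.
#' @return tibble with `cell_id`, `cluster`, `n_correct` (in `[0, n_reps]`).
#' @export
pairwise_consistency <- function(features, labels, pair, n_reps = 100,
                                 train_frac = 0.75, seed = 1L,
                                 num_trees = 100) {
  stopifnot(length(pair) == 2)
  labels <- as.integer(labels)
  idx <- which(labels %in% pair)
  sizes <- table(factor(labels[idx], levels = pair))
  n_folds <- max(2L, round(1 / (1 - train_frac)))
  if (any(sizes < n_folds)) {
    stop(sprintf("cluster pair (%s, %s) needs >= %d cells per cluster",
                 pair[1], pair[2], n_folds))
  }
  sub <- features[idx, , drop = FALSE]
  fac <- factor(labels[idx], levels = pair)
  n <- length(idx)
  n_correct <- integer(n)
  for (rep in seq_len(n_reps)) {
    rep_seed <- derive_seed(seed, "constellation", rep)
    set.seed(rep_seed)
    fold <- integer(n)
    for (cl in pair) {           # stratified fold assignment
      members <- which(fac == cl)
      fold[members] <- sample(rep_len(seq_len(n_folds), length(members)))
    }
    for (f in seq_len(n_folds)) {
      test <- fold == f
      fit <- rf_fit(sub[!test, , drop = FALSE], fac[!test], num_trees,
                    derive_seed(rep_seed, "fold", f))
      pred <- rf_predict(fit, sub[test, , drop = FALSE])
      n_correct[test] <- n_correct[test] + (pred == fac[test])
    }
  }
  tibble(
    cell_id = rownames(features)[idx] %||% as.character(idx),
    cluster = labels[idx],
    n_correct = n_correct
  )
}

#' Intermediate-cell fraction for a cluster pair
#'
#' A cell is intermediate when it was assigned to its own cluster in at most
#' `ambiguity_threshold` repetitions (i.e. NOT strictly more than 75 of
#' 100 under the defaults; a count of exactly 75 is intermediate). The
#' fraction is the percentage of the pair's cells that are intermediate.
#'
#' @param consistency tibble from [pairwise_consistency()].
#' @param ambiguity_threshold count cutoff (inclusive for intermediacy).
#' @return percentage in `[0, 100]`.
#' @export
#' @examples
#' tbl <- tibble::tibble(cell_id = letters[1:4], cluster = c(1, 1, 2, 2),
#'                       n_correct = c(100, 100, 50, 40))
#' intermediate_fraction(tbl)  # 50
intermediate_fraction <- function(consistency, ambiguity_threshold = 75) {
  100 * mean(consistency$n_correct <= ambiguity_threshold)
}

#' Build the constellation graph
#'
#' Evaluates [pairwise_consistency()] for every unordered pair of clusters
#' and summarises each pair by its intermediate-cell fraction. Nodes are
#' clusters sized by cell count; edges carry the percentage of the pair's
#' cells ambiguously assigned. Pairs in which either cluster is too small
#' for the cross-validation are skipped with a warning.
#'
#' @param features cells x d matrix of PC coordinates.
#' @param labels integer cluster labels.
#' @param config a [pipeline_config()] supplying `constellation_reps`,
#'   `constellation_train_frac`, `ambiguity_threshold` and `rf_num_trees`.
#' @param seed integer seed.
#' @return object of class `mgpop_constellation`: list with `nodes` tibble
#'   (`cluster`, `n_cells`), `edges` tibble (`cluster_a`, `cluster_b`,
#'   `n_pair`, `n_intermediate`, `intermediate_fraction`) and `consistency`
#'   (per-cell counts for audit).
#' @export
build_constellation <- function(features, labels,
                                config = pipeline_config(),
                                seed = config$seed) {
  labels <- as.integer(labels)
  clusters <- sort(unique(labels))
  nodes <- tibble(
    cluster = clusters,
    n_cells = as.integer(tabulate(match(labels, clusters), length(clusters)))
  )
  edges <- list()
  consistency <- list()
  if (length(clusters) >= 2) {
    pairs <- utils::combn(clusters, 2)
    for (p in seq_len(ncol(pairs))) {
      pair <- pairs[, p]
      cons <- tryCatch(
        pairwise_consistency(
          features, labels, pair,
          n_reps = config$constellation_reps,
          train_frac = config$constellation_train_frac,
          seed = derive_seed(seed, "pair", p),
          num_trees = config$rf_num_trees
        ),
        error = function(e) {
          warning(conditionMessage(e))
          NULL
        }
      )
      if (is.null(cons)) next
      n_int <- sum(cons$n_correct <= config$ambiguity_threshold)
      edges[[p]] <- tibble(
        cluster_a = pair[1], cluster_b = pair[2],
        n_pair = nrow(cons), n_intermediate = n_int,
        intermediate_fraction = 100 * n_int / nrow(cons)
      )
      consistency[[p]] <- mutate(cons, cluster_a = pair[1],
                                 cluster_b = pair[2])
    }
  }
  structure(
    list(
      nodes = nodes,
      edges = if (length(edges)) bind_rows(edges) else
        tibble(cluster_a = integer(), cluster_b = integer(),
               n_pair = integer(), n_intermediate = integer(),
               intermediate_fraction = double()),
      consistency = if (length(consistency)) bind_rows(consistency) else NULL
    ),
    class = "mgpop_constellation"
  )
}

#' @export
print.mgpop_constellation <- function(x, ...) {
  cat(sprintf("<mgpop_constellation> %d clusters, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  print(x$edges)
  invisible(x)
}

#' @export
tidy.mgpop_constellation <- function(x, ...) x$edges

#' Plot a constellation diagram
#'
#' Clusters on a circular layout, node area proportional to cell count,
#' edge width and opacity proportional to the intermediate-cell fraction.
#'
#' @param object an `mgpop_constellation`.
#' @param min_fraction hide edges below this intermediate percentage.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mgpop_constellation <- function(object, min_fraction = 1, ...) {
  nodes <- object$nodes
  k <- nrow(nodes)
  theta <- 2 * pi * (seq_len(k) - 1) / k
  layout <- mutate(nodes, x = cos(theta), y = sin(theta))
  edges <- object$edges |>
    filter(.data$intermediate_fraction >= min_fraction) |>
    left_join(select(layout, cluster, xa = "x", ya = "y"),
              by = c(cluster_a = "cluster")) |>
    left_join(select(layout, cluster, xb = "x", yb = "y"),
              by = c(cluster_b = "cluster"))
  p <- ggplot2::ggplot()
  if (nrow(edges)) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = .data$intermediate_fraction),
      colour = "grey60", alpha = 0.8
    )
  }
  p +
    ggplot2::geom_point(
      data = layout,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$n_cells),
      colour = "steelblue"
    ) +
    ggplot2::geom_text(
      data = layout,
      ggplot2::aes(x = 1.15 * .data$x, y = 1.15 * .data$y,
                   label = .data$cluster)
    ) +
    ggplot2::scale_size_area(max_size = 15) +
    ggplot2::scale_linewidth(range = c(0.2, 3)) +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "cells", linewidth = "% intermediate")
  }
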