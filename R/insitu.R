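# Quantification of marker-defined cell subsets from per-cell intensity
# tables (CellProfiler-style object measurements).

#' Marker-high intensity threshold
#'
#' Threshold = mean + `n_sd` x sample SD of the supplied intensities
#' (intended to be the base-marker-positive cells). Cells strictly above the
#' threshold are "high". The gate is scale-equivariant: multiplying all
#' intensities by a positive constant scales the threshold by the same
#' constant and leaves the high-cell set unchanged.
#'
#' @param intensities numeric vector (>= 2 values).
#' @param n_sd number of standard deviations above the mean.
#' @return the threshold value.
#' @export
#' @examples
#' high_expressor_threshold(c(0, 0, 0, 0, 10))  # 2 + 2 * 4.472 = 10.944
high_expressor_threshold <- function(intensities, n_sd = 2) {
  if (length(intensities) < 2) stop("need >= 2 intensity values")
  mean(intensities) + n_sd * sd(intensities)
}

#' Per-donor frequency of a marker-defined subset
#'
#' Among each donor's base-marker-positive cells, the percentage belonging
#' to the subset, defined either by a positivity flag column or by the
#' marker-high intensity gate (strictly above mean + `n_sd` SD). The
#' threshold is computed per donor by default (staining intensity is
#' donor/batch-specific) or once over all donors with `pooling = "global"`.
#' Donors without base-positive cells are excluded with a warning.
#'
#' @param table intensity tibble with at least `donor` and the referenced
#'   columns (see [simulate_intensity_table()] for the layout).
#' @param base_col name of the logical base-marker column.
#' @param subset rule: `"high"` (intensity gate) or `"flag"`.
#' @param intensity_col intensity column used when `subset = "high"`.
#' @param flag_col logical column used when `subset = "flag"`.
#' @param n_sd SD multiplier of the gate.
#' @param pooling `"donor"` or `"global"` threshold pooling.
#' @return tibble with `donor`, `n_base`, `n_subset`, `frequency`
#'   (percent), and `threshold` when the gate was used.
#' @export
subset_frequency <- function(table, base_col = "base_positive",
                             subset = c("high", "flag"),
                             intensity_col = "intensity",
                             flag_col = "true_high",
                             n_sd = 2,
                             pooling = c("donor", "global")) {
  subset <- match.arg(subset)
  pooling <- match.arg(pooling)
  base <- table[[base_col]]
  stopifnot(is.logical(base))
  empty <- setdiff(unique(table$donor), unique(table$donor[base]))
  if (length(empty)) {
    warning("donor(s) without base-positive cells excluded: ",
            paste(empty, collapse = ", "))
  }
  d <- table[base, , drop = FALSE]
  if (subset == "flag") {
    d$is_subset <- d[[flag_col]]
    d$threshold <- NA_real_
  } else if (pooling == "global") {
    thr <- high_expressor_threshold(d[[intensity_col]], n_sd)
    d$is_subset <- d[[intensity_col]] > thr
    d$threshold <- thr
  } else {
    d <- d |>
      group_by(.data$donor) |>
      mutate(
        threshold = high_expressor_threshold(.data[[intensity_col]], n_sd),
        is_subset = .data[[intensity_col]] > .data$threshold
      ) |>
      ungroup()
  }
  d |>
    group_by(.data$donor) |>
    summarise(
      n_base = n(),
      n_subset = sum(.data$is_subset),
      frequency = 100 * .data$n_subset / .data$n_base,
      threshold = .data$threshold[1],
      .groups = "drop"
    )
}

#' Compare per-donor subset frequencies between groups
#'
#' Reports both an unadjusted two-sided Welch t-test of the per-donor
#' frequencies between the two groups and a covariate-adjusted linear model
#' (frequency on group indicator + age + sex). With a group of fewer than
#' two donors the t-test cannot be computed (reported as `NA` with a
#' warning); the model still proceeds.
#'
#' @param frequencies tibble from [subset_frequency()].
#' @param covariates tibble with `donor`, `group`, `age`, `sex`.
#' @param case_group group level coded 1 in the model (default: last level).
#' @return one-row tibble with `t_p`, `mean_case`, `mean_control`,
#'   `model_coefficient`, `model_conf_low`, `model_conf_high`, `model_p`.
#' @export
compare_subset_frequency <- function(frequencies, covariates,
                                     case_group = NULL) {
  d <- left_join(frequencies, covariates, by = "donor")
  groups <- sort(unique(d$group))
  if (length(groups) != 2) stop("need exactly two donor groups")
  case_group <- case_group %||% groups[2]
  d$is_case <- as.integer(d$group == case_group)
  sizes <- table(d$group)
  t_p <- NA_real_
  if (any(sizes < 2)) {
    warning("a group has fewer than 2 donors; t-test not computable")
  } else {
    t_p <- t.test(frequency ~ is_case, data = d)$p.value
  }
  fit <- lm(frequency ~ is_case + age + sex, data = d)
  ci <- tryCatch(confint(fit, "is_case"), error = function(e) c(NA, NA))
  tibble(
    t_p = t_p,
    mean_case = mean(d$frequency[d$is_case == 1]),
    mean_control = mean(d$frequency[d$is_case == 0]),
    model_coefficient = unname(coef(fit)["is_case"]),
    model_conf_low = ci[1], model_conf_high = ci[2],
    model_p = summary(fit)$coefficients["is_case", "Pr(>|t|)"]
  )
}

#' Plaque-proximity association of a marker-defined subset
#'
#' Per donor, the subset frequency among plaque-proximal versus distal
#' base-positive cells, compared with a paired two-sided Wilcoxon
#' signed-rank test across donors. Donors lacking cells on either side of
#' the proximity flag are excluded from the pairing with a warning. The
#' marker-high gate, when used, is computed per donor over all of the
#' donor's base-positive cells (not per side).
#'
#' @inheritParams subset_frequency
#' @param proximity_col logical plaque-proximity column.
#' @return list with `per_donor` tibble (`donor`, `freq_proximal`,
#'   `freq_distal`) and `p` (paired test p-value).
#' @export
plaque_topology_association <- function(table, base_col = "base_positive",
                                        subset = c("high", "flag"),
                                        intensity_col = "intensity",
                                        flag_col = "true_high",
                                        proximity_col = "plaque_proximal",
                                        n_sd = 2) {
  subset <- match.arg(subset)
  base <- table[[base_col]]
  d <- table[base, , drop = FALSE]
  if (subset == "flag") {
    d$is_subset <- d[[flag_col]]
  } else {
    d <- d |>
      group_by(.data$donor) |>
      mutate(is_subset = .data[[intensity_col]] >
               high_expressor_threshold(.data[[intensity_col]], n_sd)) |>
      ungroup()
  }
  per_donor <- d |>
    group_by(.data$donor) |>
    summarise(
      n_proximal = sum(.data[[proximity_col]]),
      n_distal = sum(!.data[[proximity_col]]),
      freq_proximal = 100 * sum(.data$is_subset & .data[[proximity_col]]) /
        max(1, sum(.data[[proximity_col]])),
      freq_distal = 100 * sum(.data$is_subset & !.data[[proximity_col]]) /
        max(1, sum(!.data[[proximity_col]])),
      .groups = "drop"
    )
  incomplete <- per_donor$n_proximal == 0 | per_donor$n_distal == 0
  if (any(incomplete)) {
    warning("donor(s) lacking cells on one side of the proximity flag ",
            "excluded: ",
            paste(per_donor$donor[incomplete], collapse = ", "))
  }
  paired <- per_donor[!incomplete, , drop = FALSE]
  p <- if (nrow(paired) >= 2) {
    suppressWarnings(
      wilcox.test(paired$freq_proximal, paired$freq_distal,
                  paired = TRUE)$p.value
    )
  } else NA_real_
  list(per_donor = per_donor, p = p)
}
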