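#' Normalize and orient the index columns of a result table
#'
#' Puts all indices on a common 0-1 scale oriented so that higher values
#' mean stronger "significance": Bayes factors are first mapped to posterior
#' probabilities `BF / (1 + BF)` (uniform prior odds), every index column is
#' then min-max scaled to the unit interval, and the p-value, MAP-based p-value and the
#' two ROPE percentages are reversed (`1 - scaled`).
#'
#' @param table A result table as produced by [run_study()] or by row-binding
#'   [compute_index_set()] rows.
#' @param bounds `"empirical"` (min-max within the table, the default) or
#'   `"theoretical"` (fixed bounds: 0-1 for p-values, transformed Bayes
#'   factors; 50-100 for pd; 0-100 for ROPE percentages).
#' @return The table with index columns replaced by their normalized
#'   versions; attribute `"normalized"` is set.
#' @export
#' @examples
#' toy <- tibble::tibble(p_value = c(.01, .5, .9), pd = c(99.5, 75, 55),
#'                       p_map = c(.02, .6, 1), rope_95 = c(0, 40, 90),
#'                       rope_full = c(1, 42, 88), bf_0 = c(9, 1, .2),
#'                       bf_rope = c(12, 1, .1))
#' normalize_indices(toy)
normalize_indices <- function(table, bounds = c("empirical", "theoretical")) {
  bounds <- match.arg(bounds)
  if (isTRUE(attr(table, "normalized"))) return(table)  # idempotent
  cols <- intersect(index_columns(), names(table))
  if (length(cols) == 0) stop("no index columns found.", call. = FALSE)
  reversed <- c("p_value", "p_map", "rope_95", "rope_full")
  theo <- list(p_value = c(0, 1), pd = c(50, 100), p_map = c(0, 1),
               rope_95 = c(0, 100), rope_full = c(0, 100),
               bf_0 = c(0, 1), bf_rope = c(0, 1))
  out <- table
  for (v in cols) {
    val <- out[[v]]
    if (v %in% c("bf_0", "bf_rope")) val <- ifelse(is.infinite(val), 1, val / (1 + val))
    rng <- if (bounds == "theoretical") theo[[v]] else
      range(val, na.rm = TRUE, finite = TRUE)
    if (!is.finite(rng[1]) || rng[2] - rng[1] <= 0) {
      warning(sprintf("column `%s` is constant; scaled to 0.", v),
              call. = FALSE)
      sc <- rep(0, length(val))
    } else {
      sc <- (val - rng[1]) / (rng[2] - rng[1])
    }
    out[[v]] <- if (v %in% reversed) 1 - sc else sc
  }
  attr(out, "normalized") <- TRUE
  out
}

# Within-cell slope of the index on the standardized predictor(s), with the
# index standardized by `sd_ref` (the SD of the column over the reference
# scope) rather than within the cell. Returns NA when the cell is degenerate.
std_slope <- function(value, predictors, sd_ref) {
  ok <- stats::complete.cases(value, predictors)
  value <- value[ok]
  predictors <- predictors[ok, , drop = FALSE]
  if (length(value) < 3L || !is.finite(sd_ref) || sd_ref <= 0) return(NA_real_)
  if (any(vapply(predictors, function(p) stats::sd(p) == 0, logical(1)))) {
    return(NA_real_)
  }
  x <- as.data.frame(lapply(predictors, function(p) as.numeric(scale(p))))
  fit <- stats::lm.fit(cbind(1, as.matrix(x)), value / sd_ref)
  unname(fit$coefficients[2])
}

#' Sensitivity of each index to sample size
#'
#' For each index and each condition (outcome type by effect presence), the
#' standardized coefficient of the normalized index on sample size: the
#' within-condition slope, with sample size standardized within the
#' condition and the index standardized by its spread over the reference
#' scope. With `scope = "table"` (default) the index is standardized by its
#' SD over the whole table, mirroring refit-standardized simple slopes of a
#' pooled model over all conditions; `scope = "cell"` standardizes within
#' the condition, giving the plain within-cell correlation.
#'
#' @param norm A [normalize_indices()] result with `outcome_type`, `n` and
#'   `effect_present` columns.
#' @param scope Standardization scope for the index, `"table"` or `"cell"`.
#' @return A tibble with one row per index and condition: `index`,
#'   `outcome_type`, `effect_present`, `coefficient` (signed) and
#'   `sensitivity` (its magnitude). Degenerate cells are `NA`.
#' @export
sensitivity_to_n <- function(norm, scope = c("table", "cell")) {
  scope <- match.arg(scope)
  stopifnot(all(c("outcome_type", "n", "effect_present") %in% names(norm)))
  if (dplyr::n_distinct(norm$n) < 3) {
    stop("need at least 3 distinct sample sizes.", call. = FALSE)
  }
  cols <- intersect(index_columns(), names(norm))
  long <- tidyr::pivot_longer(norm, dplyr::all_of(cols),
                              names_to = "index", values_to = "value")
  ref <- dplyr::summarise(dplyr::group_by(long, .data$index),
                          sd_ref = stats::sd(.data$value, na.rm = TRUE))
  long |>
    dplyr::left_join(ref, by = "index") |>
    dplyr::group_by(.data$index, .data$outcome_type, .data$effect_present) |>
    dplyr::summarise(
      coefficient = std_slope(
        .data$value, data.frame(n = .data$n),
        if (scope == "table") .data$sd_ref[1] else
          stats::sd(.data$value, na.rm = TRUE)),
      .groups = "drop") |>
    dplyr::mutate(index = factor(.data$index, levels = cols),
                  sensitivity = abs(.data$coefficient)) |>
    dplyr::arrange(.data$index, .data$outcome_type,
                   dplyr::desc(.data$effect_present))
}

#' Sensitivity of each index to predictor noise
#'
#' For each index and outcome type, the standardized coefficient of the
#' normalized index on the noise SD, adjusted for sample size, over the
#' effect-present rows only (under the null the noise level does not alter
#' the joint data distribution). Noise and sample size are standardized
#' within the regression subset; the index is standardized by its SD over
#' the whole table (`scope = "table"`, default, as in
#' [sensitivity_to_n()]) or within the subset (`scope = "cell"`).
#'
#' @inheritParams sensitivity_to_n
#' @return A tibble with `index`, `outcome_type`, `coefficient` (signed
#'   noise coefficient) and `sensitivity` (its magnitude).
#' @export
sensitivity_to_noise <- function(norm, scope = c("table", "cell")) {
  scope <- match.arg(scope)
  stopifnot(all(c("outcome_type", "n", "effect_present", "noise_sd") %in%
                  names(norm)))
  cols <- intersect(index_columns(), names(norm))
  long <- tidyr::pivot_longer(norm, dplyr::all_of(cols),
                              names_to = "index", values_to = "value")
  ref <- dplyr::summarise(dplyr::group_by(long, .data$index),
                          sd_ref = stats::sd(.data$value, na.rm = TRUE))
  long |>
    dplyr::filter(.data$effect_present) |>
    dplyr::left_join(ref, by = "index") |>
    dplyr::group_by(.data$index, .data$outcome_type) |>
    dplyr::summarise(
      coefficient = std_slope(
        .data$value, data.frame(noise_sd = .data$noise_sd, n = .data$n),
        if (scope == "table") .data$sd_ref[1] else
          stats::sd(.data$value, na.rm = TRUE)),
      .groups = "drop") |>
    dplyr::mutate(index = factor(.data$index, levels = cols),
                  sensitivity = abs(.data$coefficient)) |>
    dplyr::arrange(.data$index, .data$outcome_type)
}

#' Probability of reaching p-value thresholds across index values
#'
#' Bins each Bayesian index into equal-count bins and computes, within each
#' bin, the empirical probability that the frequentist p-value of the same
#' dataset is at or below each threshold. The analytic pd equivalences
#' `pd = 100 * (1 - p/2)` are attached as attribute `"pd_thresholds"`.
#'
#' @param table A raw (unnormalized) result table with `p_value` and index
#'   columns.
#' @param p_thresholds P-value thresholds of interest.
#' @param n_bins Number of equal-count bins.
#' @return A tibble with `index`, `bin`, `bin_center` (median index value in
#'   the bin), `n_in_bin`, `threshold`, `probability`.
#' @export
threshold_equivalence <- function(table,
                                  p_thresholds = c(0.1, 0.05, 0.01, 0.001),
                                  n_bins = 20L) {
  stopifnot("p_value" %in% names(table))
  cols <- setdiff(intersect(index_columns(), names(table)), "p_value")
  rows <- dplyr::filter(table, is.finite(.data$p_value))
  if (nrow(rows) < n_bins) {
    warning("fewer usable rows than bins; reducing bin count.", call. = FALSE)
    n_bins <- max(1L, nrow(rows))
  }
  out <- purrr::map_dfr(cols, function(v) {
    d <- rows[is.finite(rows[[v]]) | is.infinite(rows[[v]]), ]
    val <- d[[v]]
    bin <- dplyr::ntile(val, n_bins)
    purrr::map_dfr(seq_len(n_bins), function(b) {
      inb <- bin == b
      if (!any(inb)) return(NULL)
      tibble::tibble(
        index = v, bin = b,
        bin_center = stats::median(val[inb][is.finite(val[inb])]),
        n_in_bin = sum(inb),
        threshold = p_thresholds,
        probability = vapply(p_thresholds,
                             function(t) mean(d$p_value[inb] <= t),
                             numeric(1)))
    })
  })
  attr(out, "pd_thresholds") <- tibble::tibble(
    p_threshold = p_thresholds,
    pd_threshold = 100 * (1 - p_thresholds / 2))
  out
}

#' Plot index sensitivities
#'
#' Bar chart of the sensitivity magnitudes returned by [sensitivity_to_n()]
#' or [sensitivity_to_noise()].
#'
#' @param sens A sensitivity table.
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(sens) {
  p <- ggplot2::ggplot(sens, ggplot2::aes(x = .data$index,
                                          y = .data$sensitivity))
  if ("effect_present" %in% names(sens)) {
    p <- p + ggplot2::geom_col(
      ggplot2::aes(fill = .data$effect_present), position = "dodge") +
      ggplot2::facet_wrap(~outcome_type)
  } else {
    p <- p + ggplot2::geom_col(fill = "steelblue") +
      ggplot2::facet_wrap(~outcome_type)
  }
  p + ggplot2::labs(x = NULL, y = "standardized coefficient magnitude") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot threshold-equivalence curves
#'
#' Probability of the frequentist p-value reaching each threshold as a
#' function of the binned Bayesian index value.
#'
#' @param curves A [threshold_equivalence()] result.
#' @return A ggplot object.
#' @export
plot_threshold_equivalence <- function(curves) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$bin_center, y = .data$probability,
                               linetype = factor(.data$threshold))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~index, scales = "free_x") +
    ggplot2::labs(x = "index value (bin median)",
                  y = "P(p-value below threshold)", linetype = "threshold")
}
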