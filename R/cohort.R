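#' Sample a gene cohort with gamma-distributed rates
#'
#' Draws the four free rates (`alpha_A`, `alpha_m6A`, a shared export rate
#' `beta`, and `gamma_A`) independently for each gene from a gamma
#' distribution (default shape 1, rate 1, i.e. Exponential(1)), then applies
#' a model variant to derive `beta_m6A` and `gamma_m6A` (baseline:
#' `beta_m6A = beta`, `gamma_m6A = S * gamma_A` with `S = 10`).
#'
#' The draw is fully reproducible: the same `seed` and parameters yield a
#' bit-identical cohort.
#'
#' @param n Number of genes.
#' @param shape,rate Gamma distribution parameters (both > 0).
#' @param S Decay selectivity factor for the baseline relationship.
#' @param variant Model variant applied after sampling (see
#'   [apply_variant()]).
#' @param delta Nuclear decay rate when `variant = "nuclear_decay"`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A rate table with `n` rows.
#' @examples
#' cohort <- sample_rates(100, seed = 1)
#' all(cohort$gamma_m6A == 10 * cohort$gamma_A)
#' @export
sample_rates <- function(n, shape = 1, rate = 1, S = 10,
                         variant = "baseline", delta = 1, seed = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.finite(shape) || shape <= 0 || !is.finite(rate) || rate <= 0) {
    stop("shape and rate must be positive", call. = FALSE)
  }
  draw <- function() {
    tibble::tibble(
      gene_id = sprintf("gene_%04d", seq_len(n)),
      alpha_A = stats::rgamma(n, shape = shape, rate = rate),
      alpha_m6A = stats::rgamma(n, shape = shape, rate = rate),
      beta_A = stats::rgamma(n, shape = shape, rate = rate),
      gamma_A = stats::rgamma(n, shape = shape, rate = rate)
    )
  }
  base <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  base$beta_m6A <- base$beta_A
  base$gamma_m6A <- base$gamma_A
  base$delta <- 0
  base$S <- S
  apply_variant(base, variant, S = S, delta = delta)
}

#' Steady-state pools and indices for a whole cohort
#'
#' Vectorized application of [steady_state()] and [derive_indices()] to
#' every gene of a cohort.
#'
#' @param cohort A rate table (one row per gene).
#' @return The cohort with the four pools and five derived indices appended.
#' @export
cohort_steady_state <- function(cohort) {
  steady_state_indices(cohort)
}

#' Assign near-equal-count quantile bins
#'
#' Ranks `x` with ties broken by input order (stable ranks) and cuts the
#' ranks into `n_bins` contiguous groups whose sizes differ by at most one.
#' Deterministic for any input, including heavily tied data.
#'
#' @param x Numeric vector.
#' @param n_bins Number of bins (>= 2).
#' @return An integer vector of bin ids in `1:n_bins` (1 = lowest values).
#' @examples
#' quantile_bin(1:8, 4)  # 1 1 2 2 3 3 4 4
#' @export
quantile_bin <- function(x, n_bins) {
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  if (length(x) < n_bins) {
    stop("fewer observations (", length(x), ") than bins (", n_bins, ")",
         call. = FALSE)
  }
  r <- rank(x, ties.method = "first", na.last = "keep")
  as.integer(ceiling(r * n_bins / sum(!is.na(x))))
}

#' Summarize a variable across quantile bins of another
#'
#' Bins the rows of `data` into near-equal-count quantile bins of the `by`
#' column and applies a summary statistic to the `values` column within
#' each bin.
#'
#' @param data A data frame.
#' @param values,by Columns (tidy-eval) holding the summarized variable and
#'   the binning variable.
#' @param n_bins Number of quantile bins.
#' @param statistic Summary function (default [stats::median()]).
#' @return A tibble with one row per bin: `bin`, `n`, `by_median`, `value`.
#' @examples
#' d <- tibble::tibble(x = 1:8, y = (1:8)^2)
#' bin_and_summarize(d, y, x, n_bins = 4)
#' @export
bin_and_summarize <- function(data, values, by, n_bins = 4,
                              statistic = stats::median) {
  data %>%
    dplyr::mutate(.bin = quantile_bin({{ by }}, n_bins)) %>%
    dplyr::filter(!is.na(.data$.bin)) %>%
    dplyr::group_by(bin = .data$.bin) %>%
    dplyr::summarise(
      n = dplyr::n(),
      by_median = stats::median({{ by }}, na.rm = TRUE),
      value = statistic({{ values }}[!is.na({{ values }})]),
      .groups = "drop"
    )
}

#' Two-dimensional quantile-binned summary (heatmap grid)
#'
#' Bins rows independently along two axes into quantile bins and computes a
#' summary statistic of `z` in each cell of the resulting grid. Empty cells
#' are reported with `value = NA`, never zero.
#'
#' @param data A data frame.
#' @param x,y,z Columns (tidy-eval): the two binning axes and the
#'   summarized variable.
#' @param n_bins_x,n_bins_y Bins per axis (e.g. 5 x 5 for a 25-cell grid).
#' @param statistic Summary function (default [stats::median()]).
#' @return A tibble with one row per cell: `bin_x`, `bin_y`, `n`, `value`.
#' @export
grid_heatmap <- function(data, x, y, z, n_bins_x = 5, n_bins_y = 5,
                         statistic = stats::median) {
  data %>%
    dplyr::mutate(
      bin_x = quantile_bin({{ x }}, n_bins_x),
      bin_y = quantile_bin({{ y }}, n_bins_y)
    ) %>%
    dplyr::group_by(.data$bin_x, .data$bin_y) %>%
    dplyr::summarise(
      n = sum(!is.na({{ z }})),
      value = if (sum(!is.na({{ z }})) > 0)
        statistic({{ z }}[!is.na({{ z }})]) else NA_real_,
      .groups = "drop"
    ) %>%
    tidyr::complete(
      bin_x = seq_len(n_bins_x), bin_y = seq_len(n_bins_y),
      fill = list(n = 0L, value = NA_real_)
    )
}

#' Correlation between two columns, with optional log transform
#'
#' Pearson or Spearman correlation plus its square. Ratio-type variables
#' (localization and half-life ratios) are multiplicative, so a log
#' transform prior to a Pearson fit is often appropriate.
#'
#' @param data A data frame.
#' @param x,y Columns (tidy-eval).
#' @param method `"pearson"` or `"spearman"`.
#' @param log_transform Log-transform both variables first (requires
#'   positive values; non-positive pairs are dropped).
#' @return A one-row tibble: `method`, `estimate`, `r_squared`, `n`.
#' @export
association <- function(data, x, y, method = c("pearson", "spearman"),
                        log_transform = FALSE) {
  method <- match.arg(method)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  if (log_transform) {
    keep <- !is.na(xv) & !is.na(yv) & xv > 0 & yv > 0
    xv <- log(xv[keep]); yv <- log(yv[keep])
  }
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) stop("need at least 3 paired observations",
                           call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("zero variance in one of the variables", call. = FALSE)
  }
  est <- stats::cor(xv, yv, method = method)
  tibble::tibble(method = method, estimate = est, r_squared = est^2,
                 n = length(xv))
}
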