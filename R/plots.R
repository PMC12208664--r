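#' Plot perturbation trajectories
#'
#' One line per gene of a derived index over time, on the raw or
#' normalized scale.
#'
#' @param trajectory Output of [run_perturbation_course()] (optionally
#'   passed through [normalize_trajectory()]).
#' @param y Column to plot (tidy-eval; default `m6a_level`).
#' @param color Column mapped to line color (default `gene_id`).
#' @return A ggplot object.
#' @export
plot_timecourse <- function(trajectory, y = m6a_level, color = gene_id) {
  ggplot2::ggplot(trajectory,
                  ggplot2::aes(x = .data$time, y = {{ y }},
                               color = {{ color }}, group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "time (arbitrary units)") +
    ggplot2::theme_minimal()
}

#' Plot a binned summary
#'
#' @param summary Output of [bin_and_summarize()].
#' @return A ggplot object.
#' @export
plot_binned <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = factor(.data$bin), y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "bin (low to high)", y = "summary statistic") +
    ggplot2::theme_minimal()
}

#' Plot a two-dimensional binned grid as a heatmap
#'
#' Empty cells (NA) are left blank.
#'
#' @param grid Output of [grid_heatmap()].
#' @return A ggplot object.
#' @export
plot_grid_heatmap <- function(grid) {
  ggplot2::ggplot(grid,
                  ggplot2::aes(x = factor(.data$bin_x),
                               y = factor(.data$bin_y),
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "x bin (low to high)", y = "y bin (low to high)") +
    ggplot2::theme_minimal()
}

#' Scatter of steady-state m6A level against localization for a cohort
#'
#' @param cohort_indices Output of [cohort_steady_state()].
#' @return A ggplot object (log-scaled Nuc:Cyt axis).
#' @export
plot_cohort <- function(cohort_indices) {
  ggplot2::ggplot(cohort_indices,
                  ggplot2::aes(x = .data$nuc_cyt_ratio,
                               y = .data$m6a_level)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Nuc:Cyt ratio", y = "m6A level") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("m6a_level", "gene_id"))
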