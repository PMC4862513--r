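#' Plot simulated concentration-time profiles
#'
#' Spaghetti plot of per-subject profiles on a log concentration axis,
#' coloured by hepatic group when present.
#'
#' @param profiles A long tibble from [simulate_regimen()] (columns `id`,
#'   `time`, `conc`, optionally `hepatic_group`).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles) {
  aes <- if ("hepatic_group" %in% names(profiles)) {
    ggplot2::aes(.data$time, .data$conc, group = .data$id,
                 colour = .data$hepatic_group)
  } else {
    ggplot2::aes(.data$time, .data$conc, group = .data$id)
  }
  ggplot2::ggplot(profiles[profiles$conc > 0, ], aes) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time (h)", y = "Concentration (ng/ml)",
                  colour = "Hepatic group") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of steady-state troughs
#'
#' @param troughs A tibble with columns `trough` and `hepatic_group`, e.g.
#'   from [population_troughs()] or the `"troughs"` attribute of
#'   [trough_summary()].
#' @return A ggplot object.
#' @export
plot_troughs <- function(troughs) {
  ggplot2::ggplot(troughs, ggplot2::aes(.data$hepatic_group, .data$trough,
                                        fill = .data$hepatic_group)) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA,
                          show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Steady-state trough (ng/ml)") +
    ggplot2::theme_minimal()
}

#' Diagnostic plots for normalized prediction distribution errors
#'
#' Histogram of the scores with the standard-normal density overlaid, and
#' scores against time.
#'
#' @param x An `npde_result` from [npde()].
#' @return A ggplot object (two panels via facets).
#' @export
plot_npde <- function(x) {
  s <- x$scores
  hist_df <- dplyr::mutate(s, panel = "NPDE distribution")
  time_df <- dplyr::mutate(s, panel = "NPDE vs time")
  p1 <- ggplot2::ggplot(hist_df, ggplot2::aes(.data$npde)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::stat_function(fun = stats::dnorm, linewidth = 0.8) +
    ggplot2::labs(x = "NPDE", y = "Density") +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(time_df, ggplot2::aes(.data$time, .data$npde)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = c(-1.96, 0, 1.96), linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Time (h)", y = "NPDE") +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE)) {
    p1 + p2
  } else {
    p2
  }
}

#' @export
#' @rdname plot_npde
#' @param object An `npde_result`.
#' @param ... Unused.
autoplot.npde_result <- function(object, ...) plot_npde(object)
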