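#' Plot prevalence of abundant class knowledge across cutoffs
#'
#' @param prevalence Tibble from [prevalence_table()].
#' @return A ggplot bar chart of prevalence (%) by cutoff.
#' @export
plot_prevalence <- function(prevalence) {
  ggplot2::ggplot(prevalence,
                  ggplot2::aes(x = factor(.data$cutoff), y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "Minimum series length (cutoff)",
      y = "Participants reaching cutoff (%)",
      title = "Prevalence of abundant animal class knowledge"
    ) +
    ggplot2::theme_minimal()
}

#' Plot class distributions by series-length bin
#'
#' Stacked composition of which animal classes the longest series belong
#' to, among participants reaching each length bin.
#'
#' @param distribution Tibble from [class_distribution()].
#' @return A ggplot stacked bar chart.
#' @export
plot_class_distribution <- function(distribution) {
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = factor(.data$bin), y = .data$n,
                               fill = .data$longest_class)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(
      x = "Minimum series length (bin)",
      y = "Share of participants",
      fill = "Class",
      title = "Animal classes of the longest series, by series length"
    ) +
    ggplot2::theme_minimal()
}
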