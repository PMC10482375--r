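# ggplot2 views of the result tables. Each function returns a ggplot
# object so callers can restyle or facet further.

#' Plot a differential-abundance screen
#'
#' Estimator per system type, coloured by classification; the zero line
#' separates enrichment from depletion.
#'
#' @param object a `da_result` from [diff_abundance()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.da_result <- function(object, ...) {
  df <- as_tibble(object) %>%
    arrange(estimator) %>%
    mutate(system_type = factor(system_type, levels = system_type))
  ggplot2::ggplot(df, ggplot2::aes(x = system_type, y = estimator, fill = class_label)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(
      enriched = "#d95f02", depleted = "#1f78b4",
      not_significant = "grey70", absent = "grey30"
    )) +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "differential-abundance estimator",
      fill = NULL,
      title = sprintf("Differential abundance vs background (focal: %s)", attr(object, "focal"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot normalized positions along linear replicons
#'
#' Histogram of normalized start positions per system type; extremity bands
#' at the given threshold are shaded.
#'
#' @param positions tibble from [normalized_positions()].
#' @param threshold extremity threshold to shade (default 0.1).
#' @param bins histogram bins (default 40).
#' @return a ggplot object.
#' @export
plot_spatial_positions <- function(positions, threshold = 0.1, bins = 40) {
  check_columns(positions, c("system_type", "position"), "positions")
  ggplot2::ggplot(positions, ggplot2::aes(x = position)) +
    ggplot2::annotate("rect",
      xmin = -Inf, xmax = threshold, ymin = -Inf, ymax = Inf,
      fill = "grey85", alpha = 0.6
    ) +
    ggplot2::annotate("rect",
      xmin = 1 - threshold, xmax = Inf, ymin = -Inf, ymax = Inf,
      fill = "grey85", alpha = 0.6
    ) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "#1f78b4") +
    ggplot2::facet_wrap(~system_type, scales = "free_y") +
    ggplot2::labs(
      x = "normalized position on linear replicon", y = "occurrences",
      title = "Spatial distribution along linear replicons"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the per-type contribution of genetic elements
#'
#' Stacked bars of the chromosome / plasmid / prophage fractions per system
#' type, annotated with the total occurrence count.
#'
#' @param contribution tibble from [mge_contribution()].
#' @return a ggplot object.
#' @export
plot_mge_contribution <- function(contribution) {
  check_columns(
    contribution,
    c("system_type", "n_total", "fraction_chromosome", "fraction_plasmid", "fraction_prophage"),
    "contribution"
  )
  long <- contribution %>%
    arrange(fraction_chromosome) %>%
    mutate(system_type = factor(system_type, levels = system_type)) %>%
    tidyr::pivot_longer(
      cols = c(fraction_chromosome, fraction_plasmid, fraction_prophage),
      names_to = "element", values_to = "fraction", names_prefix = "fraction_"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = system_type, y = fraction, fill = element)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(
      data = distinct(long, system_type, n_total),
      ggplot2::aes(x = system_type, y = 1.02, label = n_total),
      inherit.aes = FALSE, size = 2.8, vjust = 0
    ) +
    ggplot2::scale_fill_manual(values = c(
      chromosome = "grey75", plasmid = "#33a02c", prophage = "#6a3d9a"
    )) +
    ggplot2::labs(
      x = NULL, y = "fraction of occurrences", fill = NULL,
      title = "Contribution of genetic elements per system type"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
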