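#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of the differential-expression meta-analysis
#'
#' Pooled effect size against -log10 FDR (route 1), colored by the
#' two-route consensus call.
#'
#' @param object A `meta_de` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meta_de <- function(object, ...) {
  tab <- object$table |>
    dplyr::filter(!is.na(.data$pooled_es), !is.na(.data$q_es)) |>
    dplyr::mutate(call = dplyr::case_when(
      .data$consensus & .data$direction == "up" ~ "up in spinal",
      .data$consensus & .data$direction == "down" ~ "down in spinal",
      TRUE ~ "not significant"
    ))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$pooled_es,
                                    y = -log10(pmax(.data$q_es, 1e-300)),
                                    colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      "up in spinal" = "#c0392b", "down in spinal" = "#27ae60",
      "not significant" = "grey70")) +
    ggplot2::labs(x = "pooled effect size (spinal - intracranial)",
                  y = expression(-log[10] ~ FDR),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a kernel-smoothed chromosome expression profile
#'
#' @param profile Tibble from [chromosome_profile()].
#' @param points Optional tibble with `position` and `value` columns (e.g.
#'   per-gene pooled effects at gene midpoints) drawn under the curve.
#' @param region Optional numeric `c(start, end)` shaded interval (bp).
#' @return A ggplot.
#' @export
plot_chromosome_profile <- function(profile, points = NULL, region = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$position / 1e6,
                                             y = .data$smoothed))
  if (!is.null(region)) {
    p <- p + ggplot2::annotate("rect", xmin = region[1] / 1e6,
                               xmax = region[2] / 1e6,
                               ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "#27ae60")
  }
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(
      data = points,
      ggplot2::aes(x = .data$position / 1e6, y = .data$value),
      inherit.aes = FALSE, alpha = 0.4, size = 0.7, colour = "grey50")
  }
  p + ggplot2::geom_line(colour = "#8e44ad", linewidth = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "position (Mb)", y = "smoothed statistic") +
    ggplot2::theme_minimal()
}

#' Seed-connectivity prioritization plot
#'
#' Within-seed-set degree against -log10 permutation p, highlighting seeds
#' prioritized at p < 0.05.
#'
#' @param object A `seed_connectivity` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.seed_connectivity <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$degree_in_seed_subgraph,
                               y = -log10(.data$p_perm),
                               colour = .data$prioritized)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = 2,
                        colour = "grey60") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "direct links to other seeds",
                  y = expression(-log[10] ~ p[perm]),
                  colour = "p < 0.05") +
    ggplot2::theme_minimal()
}
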