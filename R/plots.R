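#' Plot family totals by age class
#'
#' Bar chart of total relative concentration per chemical family, dodged by
#' age class, on a log10 axis (family totals span several orders of
#' magnitude, from norisoprenoids to acids).
#'
#' @param families An [aggregate_families()] result.
#' @return A ggplot object.
#' @export
plot_family_aggregates <- function(families) {
  ggplot2::ggplot(families,
                  ggplot2::aes(x = stats::reorder(.data$family,
                                                  .data$total_rel_conc_ug_per_L),
                               y = .data$total_rel_conc_ug_per_L,
                               fill = .data$age_class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Total relative concentration (µg/L)",
                  fill = "Age class") +
    ggplot2::theme_minimal()
}

#' Plot per-compound Kovats deviations
#'
#' Lollipop chart of |KIcalc - KIlit| for every library compound with a
#' literature KI, with the default matching tolerance marked.
#'
#' @param report A [ki_deviation_report()].
#' @param abs_tol Tolerance line to draw, index units.
#' @return A ggplot object.
#' @export
plot_ki_deviation <- function(report, abs_tol = 35) {
  tbl <- tidy(report)
  ggplot2::ggplot(tbl, ggplot2::aes(x = stats::reorder(.data$compound_id,
                                                       .data$delta_ki),
                                    y = .data$delta_ki)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$compound_id, yend = 0),
                          color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(color = .data$family)) +
    ggplot2::geom_hline(yintercept = abs_tol, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "|KI calculated - KI literature|",
                  color = "Family") +
    ggplot2::theme_minimal(base_size = 8)
}

#' Heatmap of a projection's shared-compound weights
#'
#' @param object An `aroma_projection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot aroma_projection
#' @export
autoplot.aroma_projection <- function(object, ...) {
  edges <- tidy(object)
  sym <- bind_rows(edges, rename(edges, from = "to", to = "from"))
  ggplot2::ggplot(sym, ggplot2::aes(x = .data$from, y = .data$to,
                                    fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$weight), size = 3) +
    ggplot2::scale_fill_gradient(low = "#fee8c8", high = "#e34a33") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Shared VOCs",
                  title = paste(attr(object, "level"), "projection")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
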