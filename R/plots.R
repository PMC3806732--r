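#' Ordination scatter plot
#'
#' Plots the first two NMDS axes, optionally coloured by group; the
#' stress is shown in the subtitle.
#'
#' @param object A `microsig_nmds` from [nmds()].
#' @param labels Optional tibble `sample_id`, `group` for colouring.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot microsig_nmds
#' @export
autoplot.microsig_nmds <- function(object, labels = NULL, ...) {
  d <- object$points
  if (object$k < 2L) d$NMDS2 <- 0
  if (!is.null(labels)) {
    d$group <- align_labels(labels, d$sample_id)
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$NMDS1, .data$NMDS2,
                                         colour = .data$group))
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$NMDS1, .data$NMDS2))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(subtitle = sprintf("stress = %.3g", object$stress)) +
    ggplot2::theme_minimal()
}

#' Diversity and equitability by group
#'
#' Boxplots of Shannon diversity and equitability per group, the standard
#' display for spotting a group with depressed diversity.
#'
#' @param div Tibble from [diversity_table()].
#' @param labels Tibble `sample_id`, `group`.
#' @return A ggplot object (two facets).
#' @export
plot_diversity <- function(div, labels) {
  d <- div |>
    dplyr::mutate(group = align_labels(labels, .data$sample_id)) |>
    tidyr::pivot_longer(c("shannon", "equitability"),
                        names_to = "index", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$value,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap
#'
#' @param object A `microsig_classification` from
#'   [score_classification()] or [classify_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot microsig_classification
#' @export
autoplot.microsig_classification <- function(object, ...) {
  d <- as.data.frame(object$confusion)
  ggplot2::ggplot(d, ggplot2::aes(.data$predicted, .data$truth,
                                  fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey20", high = "steelblue") +
    ggplot2::labs(title = sprintf("accuracy = %.2f", object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Prevalence heatmap of signature taxa
#'
#' Tile plot of per-group prevalence for the taxa in any group's
#' signature set, split by Venn region.
#'
#' @param prev Prevalence table from [prevalence()].
#' @param sigs A `microsig_signatures` from [group_signatures()].
#' @return A ggplot object.
#' @export
plot_signatures <- function(prev, sigs) {
  keep <- prev$taxon %in% sigs$regions$taxon
  d <- prev[keep, setdiff(names(prev), "overall")] |>
    tidyr::pivot_longer(-"taxon", names_to = "group",
                        values_to = "prevalence") |>
    dplyr::left_join(sigs$regions, by = "taxon")
  ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$taxon,
                                  fill = .data$prevalence)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(region ~ ., scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.text.y = ggplot2::element_text(angle = 0))
}
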