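# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_step
#'   geom_vline labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a tag-density metaprofile
#'
#' @param object A `cistromer_profile` from [tag_density_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cistromer_profile <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$offset, y = .data$density)) +
    geom_line(colour = "#2c7fb8") +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    labs(x = "distance from anchor (bp)",
         y = "weighted tags / bp / region",
         title = sprintf("Tag density around %d anchors",
                         attr(object, "n_anchors") %||% NA)) +
    theme_minimal()
}

#' Plot SOM node profiles
#'
#' Mean codebook profile per node with node occupancy in the strip label.
#'
#' @param object A `cistromer_som` from [som_cluster()].
#' @param timepoints Optional x-axis values (defaults to column index).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cistromer_som <- function(object, timepoints = NULL, ...) {
  k <- nrow(object$codes)
  tp <- timepoints %||% seq_len(ncol(object$codes))
  occ <- table(factor(object$labels, levels = seq_len(k)))
  df <- tibble(
    node = rep(sprintf("node %d (n=%d)", seq_len(k), as.integer(occ)),
               each = length(tp)),
    timepoint = rep(tp, k),
    value = as.vector(t(object$codes)))
  ggplot(df, aes(x = .data$timepoint, y = .data$value)) +
    geom_line() +
    facet_wrap(~node) +
    labs(x = "time point (h)", y = "mean log2 fold change",
         title = "SOM regulation clusters") +
    theme_minimal()
}

#' Cumulative TSS-distance curves for up- vs down-regulated genes
#'
#' Empirical CDFs of absolute region-to-TSS distances, the display behind
#' the two-sample KS comparison.
#'
#' @param dists_up,dists_down Numeric distance vectors in bp.
#' @return A ggplot.
#' @export
plot_distance_ecdf <- function(dists_up, dists_down) {
  df <- bind_rows(
    tibble(distance = abs(dists_up) / 1000, group = "up-regulated"),
    tibble(distance = abs(dists_down) / 1000, group = "down-regulated"))
  ggplot(df, aes(x = .data$distance, colour = .data$group)) +
    geom_step(stat = "ecdf") +
    labs(x = "distance to TSS (kb)", y = "cumulative fraction",
         colour = NULL) +
    theme_minimal()
}

#' Bar chart of a binding-characteristics summary
#'
#' @param report Output of [summarize_binding()].
#' @return A ggplot of the percentage rows.
#' @export
plot_summary_percent <- function(report) {
  df <- filter(report, !is.na(.data$percent),
               !grepl("density", .data$statistic))
  ggplot(df, aes(x = stats::reorder(.data$statistic, .data$percent),
                 y = .data$percent)) +
    geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "percent") +
    theme_minimal()
}
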