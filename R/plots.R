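#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot rank shifts between two transformation schemes
#'
#' Species ordered by their reference-scheme rank against the signed rank
#' difference (alternative minus reference); negative values mean the
#' reference scheme prioritizes the species. The shaded band marks the
#' equivalence zone (|delta| <= 10 by default upstream).
#'
#' @param rank_deltas Tibble from [rank_difference()].
#' @param categories Optional tibble `species`, `raw_category` to colour
#'   points by Red List category.
#' @param equivalence Half-width of the shaded equivalence band.
#' @return A ggplot object.
#' @export
plot_rank_shift <- function(rank_deltas, categories = NULL,
                            equivalence = 10) {
  df <- rank_deltas
  if (!is.null(categories)) {
    df <- dplyr::left_join(df, categories, by = "species")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank_reference,
                                        y = .data$delta)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = -equivalence, ymax = equivalence,
                      alpha = 0.15) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40")
  p <- if ("raw_category" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$raw_category),
                            alpha = 0.7)
  } else {
    p + ggplot2::geom_point(alpha = 0.7)
  }
  p + ggplot2::labs(x = "rank under reference scheme",
                    y = "rank difference (alternative - reference)",
                    colour = "IUCN category") +
    ggplot2::theme_minimal()
}

#' Plot regional over/under-representation of top-ranked species
#'
#' Observed top-set counts against the richness-proportional expectation;
#' point size encodes regional richness, colour the direction, and filled
#' points are significant under the exact binomial test.
#'
#' @param regions Tibble from [hotspot_classification()].
#' @return A ggplot object.
#' @export
plot_region_hotspots <- function(regions) {
  ggplot2::ggplot(regions,
                  ggplot2::aes(x = .data$expected, y = .data$top_count)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(size = .data$richness,
                                     colour = .data$direction,
                                     alpha = .data$significant)) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35)) +
    ggplot2::scale_colour_manual(values = c(more = "#2166AC",
                                            fewer = "#B2182B",
                                            neither = "grey50")) +
    ggplot2::labs(x = "expected top-set count (richness-proportional)",
                  y = "observed top-set count",
                  colour = "direction", alpha = "significant",
                  size = "richness") +
    ggplot2::theme_minimal()
}

#' Autoplot a fitted prioritization
#'
#' @param object An `edge_prioritization` object.
#' @param type `"rank_shift"` (scheme comparison), `"regions"` (top-EDGE
#'   hotspots), or `"ed"` (median-ED distribution by category).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.edge_prioritization <- function(object,
                                         type = c("rank_shift", "regions",
                                                  "ed"),
                                         ...) {
  type <- match.arg(type)
  switch(type,
         rank_shift = {
           if (is.null(object$rank_deltas)) {
             stop("pipeline was run with a single scheme; no rank shifts",
                  call. = FALSE)
           }
           plot_rank_shift(object$rank_deltas,
                           object$scores[, c("species", "raw_category")])
         },
         regions = plot_region_hotspots(object$regions_edge),
         ed = ggplot2::ggplot(object$scores,
                              ggplot2::aes(x = .data$raw_category,
                                           y = .data$median_ed)) +
           ggplot2::geom_boxplot(outlier.alpha = 0.4) +
           ggplot2::scale_y_log10() +
           ggplot2::labs(x = "IUCN category", y = "median ED (Myr)") +
           ggplot2::theme_minimal())
}
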