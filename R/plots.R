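# ggplot2 visualisations for the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_col scale_alpha_identity labs facet_wrap theme_minimal
#'   scale_fill_gradient2 coord_equal
#' @export
ggplot2::autoplot

#' Plot an AUC-vs-k niche selection curve
#'
#' @param object An `auc_curve` from [select_k_niches()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.auc_curve <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$k, y = .data$mean_auc)) +
    geom_line(colour = "grey40") +
    geom_point(size = 2) +
    labs(x = "number of niches (k)", y = "mean holdout AUC") +
    theme_minimal()
}

#' Plot niche centroid compositions
#'
#' Heatmap of broad-type fractions per niche centroid.
#'
#' @param object A `niche_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.niche_result <- function(object, ...) {
  ggplot(tidy(object),
         aes(x = .data$broad, y = .data$niche, fill = .data$fraction)) +
    geom_tile() +
    scale_fill_gradient2(low = "white", high = "darkred", midpoint = 0) +
    labs(x = NULL, y = NULL, fill = "fraction") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot ring-neighborhood expression profiles
#'
#' @param profiles Output of [ring_profile_matrix()] (or a single
#'   [ring_profile()] tibble, in which case raw means are drawn).
#' @return A ggplot of standardized (or raw) expression against ring index.
#' @export
plot_ring_profiles <- function(profiles) {
  if ("z" %in% names(profiles)) {
    ggplot(profiles, aes(x = .data$k, y = .data$z, colour = .data$module)) +
      geom_line() + geom_point() +
      labs(x = "ring index k", y = "standardized mean expression") +
      theme_minimal()
  } else {
    ggplot(profiles, aes(x = .data$k, y = .data$mean_expr)) +
      geom_line() + geom_point() +
      labs(x = "ring index k", y = "mean expression") +
      theme_minimal()
  }
}

#' Dot plot of called ligand-receptor interactions
#'
#' Interaction potential maps to point size and the rendering transparency
#' (1 - alpha) comes straight from [ribbon_transparency()], so the
#' strongest interaction is fully opaque.
#'
#' @param interactions An `interaction_set` from [call_interactions()].
#' @return A ggplot.
#' @export
plot_interactions <- function(interactions) {
  ggplot(interactions,
         aes(x = .data$receiver,
             y = paste(.data$ligand, "→", .data$receptor),
             size = .data$potential,
             alpha = 1 - .data$transparency)) +
    geom_point(colour = "steelblue") +
    scale_alpha_identity() +
    labs(x = "receiver subtype", y = NULL, size = "potential") +
    theme_minimal()
}

#' Spatial map of niche assignments
#'
#' @param cells Tibble with `x`, `y`, `spot_id` and a `niche` column (e.g.
#'   cells joined with a `niche_result` assignment).
#' @return A ggplot faceted by spot.
#' @export
plot_niche_map <- function(cells) {
  ggplot(cells, aes(x = .data$x, y = .data$y, colour = .data$niche)) +
    geom_point(size = 0.4) +
    facet_wrap(~spot_id) +
    coord_equal() +
    labs(colour = "niche") +
    theme_minimal()
}
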