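#' Scree plot of a PCA fit
#'
#' Eigenvalues against component rank, with the Kaiser reference line at 1.
#'
#' @param object A `qoc_pca` object.
#' @param n_components Number of leading components to show (default: all).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qoc_pca
#' @export
autoplot.qoc_pca <- function(object, n_components = NULL, ...) {
  df <- scree_table(object)
  if (!is.null(n_components)) df <- df[seq_len(min(n_components, nrow(df))), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$eigenvalue)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Component", y = "Eigenvalue",
                  title = "Scree plot",
                  subtitle = sprintf("%d components with eigenvalue ≥ 1",
                                     object$kaiser_count)) +
    ggplot2::theme_minimal()
}

#' Score distributions by mechanism
#'
#' Histograms of the three facility scores; additive scores often heap on a
#' few values, which is why tercile groups can be unequal.
#'
#' @param scores A `qoc_scores` tibble.
#' @return A ggplot object faceted by scoring mechanism (free x scales).
#' @export
plot_score_distributions <- function(scores) {
  long <- tidyr::pivot_longer(
    as_tibble(scores)[, c("simple_additive", "weighted_additive", "pca_score")],
    dplyr::everything(), names_to = "score", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~score, scales = "free_x") +
    ggplot2::labs(x = "Score", y = "Facilities") +
    ggplot2::theme_minimal()
}

#' High-quality profile bar chart
#'
#' Percent of facilities ranked high by each mechanism within each stratum of
#' the background characteristics.
#'
#' @param profile A profile tibble from [high_quality_profile()].
#' @return A ggplot object.
#' @export
plot_high_quality_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$stratum, y = .data$pct_high,
                               fill = .data$score)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~characteristic, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "% of facilities ranked high", fill = "Index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
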