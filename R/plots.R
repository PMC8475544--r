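# ggplot2 views of grids, response curves, evaluations and contributions.

#' Plot a grid as a raster map
#'
#' @param object A `bgrid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bgrid <- function(object, ...) {
  df <- as_tibble.bgrid(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$name) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
}

#' Plot response curves
#'
#' @param curves Tibble from [response_curves()].
#' @return A ggplot, one facet per variable.
#' @export
plot_response_curves <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$x, y = .data$suitability)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Variable value", y = "Habitat suitability") +
    ggplot2::theme_minimal()
}

#' Plot per-run test metrics of an evaluation
#'
#' @param object An `sdm_evaluation` or `sdm_ensemble_evaluation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sdm_ensemble_evaluation <- function(object, ...) {
  long <- tidyr::pivot_longer(object$runs, c("auc", "tss"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Held-out score") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sdm_ensemble_evaluation
#' @export
autoplot.sdm_evaluation <- function(object, ...) {
  long <- tidyr::pivot_longer(object$runs, c("auc", "tss"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::labs(x = NULL, y = "Held-out score", title = object$learner) +
    ggplot2::theme_minimal()
}

#' Plot permutation variable contributions
#'
#' @param contrib Tibble from [variable_contribution()].
#' @return A ggplot bar chart.
#' @export
plot_contributions <- function(contrib) {
  ggplot2::ggplot(
    contrib,
    ggplot2::aes(x = stats::reorder(.data$variable, .data$contribution),
                 y = .data$contribution)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Contribution (%)") +
    ggplot2::theme_minimal()
}
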