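#' Tidy a propagation result
#'
#' @param x A `propagation_result` from [permutation_zscores()].
#' @param ... Unused.
#' @return A plain tibble sorted by decreasing z-score, with the context
#'   as a column.
#' @exportS3Method generics::tidy
tidy.propagation_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$context <- attr(x, "context")
  dplyr::arrange(out, dplyr::desc(.data$z))
}

#' One-row summary of a propagation result
#'
#' @param x A `propagation_result`.
#' @param ... Unused.
#' @return Tibble with node count, permutation count, restart probability,
#'   the maximum z-score and the number of nodes above the configured
#'   z threshold.
#' @exportS3Method generics::glance
glance.propagation_result <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(context = attr(x, "context"), n_nodes = nrow(x),
                 n_perm = cfg$n_perm, restart_prob = cfg$restart_prob,
                 max_z = max(x$z), n_enriched = sum(x$z > cfg$z_thresh))
}

#' Plot the top enriched nodes of a propagation result
#'
#' @param object A `propagation_result`.
#' @param n_top Number of top-z nodes to show.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.propagation_result <- function(object, n_top = 20, ...) {
  df <- tidy(object) |> dplyr::slice_head(n = n_top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$z, y = stats::reorder(.data$node, .data$z))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "permutation z-score", y = NULL,
                  title = sprintf("Top propagated nodes (%s)",
                                  attr(object, "context"))) +
    ggplot2::theme_minimal()
}

#' Plot a hexagonal spot grid
#'
#' @param object A `hex_grid`.
#' @param ... Unused.
#' @return A ggplot with y reversed to match image coordinates.
#' @exportS3Method ggplot2::autoplot
autoplot.hex_grid <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a spot annotation coloured by axis value
#'
#' @param spot_ann Tibble with `x`, `y` and `axis` columns (from
#'   [compute_axis()]).
#' @return A ggplot in image coordinates with a rainbow axis scale.
#' @export
plot_axis <- function(spot_ann) {
  stopifnot("axis" %in% names(spot_ann))
  ggplot2::ggplot(spot_ann, ggplot2::aes(.data$x, .data$y,
                                         colour = .data$axis)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_gradientn(colours = grDevices::rainbow(7)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "axis") +
    ggplot2::theme_minimal()
}
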