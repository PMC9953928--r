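#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Render a height map
#'
#' @param object a [heightmap()].
#' @param ... unused.
#' @return A ggplot raster of z over physical coordinates.
#' @method autoplot heightmap
#' @export
autoplot.heightmap <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = paste0("z [", object$value_units, "]")) +
    ggplot2::labs(
      x = "x [µm]", y = "y [µm]",
      title = if (is.na(object$sample_id)) NULL else object$sample_id
    ) +
    ggplot2::theme_minimal()
}

#' Render a 2D RMS-deviation map
#'
#' @param object a `vgram_map` from [rms_deviation_map()].
#' @param ... unused.
#' @return A ggplot tile map of D over signed lag vectors (v, p).
#' @method autoplot vgram_map
#' @export
autoplot.vgram_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$v, .data$p, fill = .data$d)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(
      name = paste0("D(h) [", attr(object, "value_units"), "]"),
      na.value = "white") +
    ggplot2::labs(x = "v [px]", y = "p [px]") +
    ggplot2::theme_minimal()
}

#' Render a radial variogram curve
#'
#' @param object a `vgram_1d` from [radial_variogram()].
#' @param ... unused.
#' @return A ggplot line of gamma against lag.
#' @method autoplot vgram_1d
#' @export
autoplot.vgram_1d <- function(object, ...) {
  q <- attr(object, "moment_q")
  ggplot2::ggplot(dplyr::filter(object, .data$n_pairs > 0),
                  ggplot2::aes(.data$lag_um, .data$gamma)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "lag |h| [µm]",
                  y = sprintf("γ(h, q = %s)", format(q))) +
    ggplot2::theme_minimal()
}

#' Render a theta distribution
#'
#' @param object a [theta_distribution()].
#' @param ... unused.
#' @return A ggplot histogram of facet inclination density.
#' @method autoplot theta_distribution
#' @export
autoplot.theta_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$theta_deg, .data$density)) +
    ggplot2::geom_col(width = attr(object, "bin_width_deg")) +
    ggplot2::labs(
      x = "facet inclination θ [deg]", y = "density",
      subtitle = sprintf("skewness %.2f, excess kurtosis %.2f",
                         attr(object, "skewness"), attr(object, "kurtosis"))
    ) +
    ggplot2::theme_minimal()
}

#' Render a sill classification with its threshold line
#'
#' Per-sample sills by group, the two group means and the midpoint threshold
#' (samples above the line are called non-metastatic, below metastatic).
#'
#' @param object a [fit_threshold()] result.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot sill_classifier
#' @export
autoplot.sill_classifier <- function(object, ...) {
  calls <- object$calls
  ggplot2::ggplot(calls,
                  ggplot2::aes(.data$sample_id, .data$sill,
                               colour = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$threshold, colour = "black") +
    ggplot2::geom_hline(yintercept = object$group_mean_met,
                        colour = "red", linetype = 2) +
    ggplot2::geom_hline(yintercept = object$group_mean_nonmet,
                        colour = "blue", linetype = 2) +
    ggplot2::labs(x = NULL, y = sprintf("sill (q = %s)", format(object$q)),
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
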