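#' Plot an orientation histogram
#'
#' Polar-angle view of the spherical histogram: face density against the
#' polar angle of the face centroid, coloured by density.
#'
#' @param object An `orientation_histogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot orientation_histogram
autoplot.orientation_histogram <- function(object, ...) {
  df <- tibble(
    theta = acos(pmin(1, abs(object$nz))) * 180 / pi,
    density = object$density
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$density)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(
      x = "face polar angle from z (degrees)",
      y = expression(density ~ (sr^-1)),
      title = "Orientation distribution"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a diameter profile
#'
#' @param object Tibble from [diameter_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_diameter_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$segment, y = .data$diameter)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "slice", y = "equivalent diameter (um)") +
    ggplot2::theme_minimal()
}

#' Plot phantom skeletons (2D projection)
#'
#' @param object A `phantom`.
#' @param plane Projection plane, `"xz"`, `"yz"` or `"xy"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot phantom
autoplot.phantom <- function(object, plane = "xz", ...) {
  pts <- tidy(object)
  ax <- strsplit(plane, "")[[1]]
  ggplot2::ggplot(pts, ggplot2::aes(
    x = .data[[ax[1]]], y = .data[[ax[2]]],
    group = .data$fibre, colour = factor(.data$bundle)
  )) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "bundle", x = paste0(ax[1], " (um)"),
                  y = paste0(ax[2], " (um)")) +
    ggplot2::theme_minimal()
}

#' Plot ablation results
#'
#' @param object Tibble from [run_ablation_experiment()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_ablation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$mechanisms, y = 100 * .data$mean_density
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = 100 * (.data$mean_density - .data$se_density),
      ymax = 100 * (.data$mean_density + .data$se_density)
    ), width = 0.2) +
    ggplot2::facet_wrap(~ .data$scenario) +
    ggplot2::labs(x = NULL, y = "achieved density (%)") +
    ggplot2::theme_minimal()
}

#' Plot a virtual histology slice
#'
#' @param object A `histology_slice`.
#' @param max_px Downsample the image to at most this many pixels per side
#'   for display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot histology_slice
autoplot.histology_slice <- function(object, max_px = 600, ...) {
  img <- object$image
  step <- max(1L, ceiling(max(dim(img)) / max_px))
  img <- img[seq(1, nrow(img), by = step), seq(1, ncol(img), by = step)]
  df <- tibble(
    u = rep(seq_len(ncol(img)), each = nrow(img)),
    v = rep(seq_len(nrow(img)), ncol(img)),
    label = as.vector(img)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v,
                                   fill = factor(.data$label))) +
    ggplot2::geom_raster(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c("0" = "white",
      setNames(grDevices::hcl.colors(max(1, length(unique(df$label)) - 1),
                                     "Spectral"),
               setdiff(unique(df$label), 0)))) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
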