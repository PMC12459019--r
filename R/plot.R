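#' Maximum intensity projection of a rendered image
#'
#' @param image A [render_density()] `ulm_image` or [render_velocity()]
#'   `velocity_map`.
#' @param axis Projection axis: 3 (elevation, the transverse view),
#'   2 (lateral) or 1 (depth).
#' @return A tibble with the projected plane coordinates in mm and the
#'   projected `value`.
#' @export
mip <- function(image, axis = 3) {
  arr <- if (inherits(image, "velocity_map")) image$speed else image$density
  v <- image$render_voxel_mm
  m <- apply(arr, setdiff(1:3, axis), max)
  ax <- setdiff(1:3, axis)
  nm <- c("depth_mm", "lateral_mm", "elevation_mm")
  out <- tidyr::expand_grid(
    a = voxel_center_mm(seq_len(dim(m)[1]), v),
    b = voxel_center_mm(seq_len(dim(m)[2]), v))
  out$value <- as.vector(t(matrix(m, dim(m)[1], dim(m)[2])))
  names(out)[1:2] <- nm[ax]
  out
}

#' Plot a maximum intensity projection
#'
#' Transverse-view MIP of a density image or velocity map, the standard
#' way ULM reconstructions are displayed.
#'
#' @param object A `ulm_image` or `velocity_map`.
#' @param axis Projection axis (default 3, elevation).
#' @param trans Intensity transform for display (`"sqrt"` by default for
#'   density; use `"identity"` for speed maps).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ulm_image <- function(object, axis = 3, trans = "sqrt", ...) {
  df <- mip(object, axis)
  nm <- names(df)[1:2]
  ggplot2::ggplot(df, ggplot2::aes(.data[[nm[2]]], .data[[nm[1]]],
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(trans = trans, option = "inferno",
                                  name = "tracks") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = nm[2], y = nm[1]) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ulm_image
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.velocity_map <- function(object, axis = 3, trans = "identity", ...) {
  df <- mip(object, axis)
  nm <- names(df)[1:2]
  ggplot2::ggplot(df, ggplot2::aes(.data[[nm[2]]], .data[[nm[1]]],
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(trans = trans, name = "mm/s") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = nm[2], y = nm[1]) +
    ggplot2::theme_minimal()
}

#' Plot hemisphere shell-speed profiles
#'
#' Left/right mean speed (top) and their difference (bottom) against
#' shell radius, the display used to read localized hemodynamic
#' reduction: a tumoral-side slowdown appears as negative differences at
#' small radii.
#'
#' @param lhr Shell-profile tibble from [shell_profiles()] or
#'   `tidy()` of an `ulm_metrics`.
#' @return A ggplot.
#' @export
plot_shell_profiles <- function(lhr) {
  long <- tidyr::pivot_longer(
    lhr, c("mean_speed_left", "mean_speed_right"),
    names_to = "side", values_to = "mean_speed",
    names_prefix = "mean_speed_")
  ggplot2::ggplot(long, ggplot2::aes(.data$radius_mm, .data$mean_speed,
                                     colour = .data$side)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "shell outer radius (mm)",
                  y = "mean speed (mm/s)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_shell_profiles
#' @param object An `ulm_metrics` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ulm_metrics <- function(object, ...) plot_shell_profiles(object$lhr)

#' Plot a vessel network (lateral-elevation projection)
#'
#' @param object A `vessel_network`.
#' @param ... Unused.
#' @return A ggplot with segments coloured by centerline speed.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.vessel_network <- function(object, ...) {
  ggplot2::ggplot(object) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$x0_mm, y = .data$y0_mm,
      xend = .data$x1_mm, yend = .data$y1_mm,
      colour = .data$speed_mm_s, linewidth = .data$radius_mm)) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::scale_colour_viridis_c(name = "mm/s") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "lateral (mm)", y = "elevation (mm)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
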