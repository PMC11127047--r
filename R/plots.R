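#' Convert grid fields to a long tibble
#'
#' @param x A [nematic_field()] or [flow_field()].
#' @param ... Unused.
#' @return Tibble with columns `x`, `y` and the field values (`S`, `theta`
#'   for a nematic field; `ux`, `uy`, `omega`, `speed` for a flow field).
#' @export
field_tibble <- function(x, ...) UseMethod("field_tibble")

#' @export
field_tibble.nematic_field <- function(x, ...) {
  g <- x$grid
  tibble::tibble(x = rep(g$x, g$ny), y = rep(g$y, each = g$nx),
                 S = as.vector(order_S(x)),
                 theta = as.vector(director_angle(x)))
}

#' @export
field_tibble.flow_field <- function(x, ...) {
  g <- x$grid
  tibble::tibble(x = rep(g$x, g$ny), y = rep(g$y, each = g$nx),
                 ux = as.vector(x$ux), uy = as.vector(x$uy),
                 omega = as.vector(x$omega),
                 speed = as.vector(sqrt(x$ux^2 + x$uy^2)))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a nematic field (order parameter and defects)
#'
#' Heat map of S with detected defects overlaid (+1/2 circles with polarity
#' segments, -1/2 triangles).
#'
#' @param object A [nematic_field()].
#' @param defects Optional precomputed defect table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nematic_field <- function(object, defects = NULL, ...) {
  df <- field_tibble(object)
  if (is.null(defects)) defects <- detect_defects(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$S)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y", fill = "S")
  if (nrow(defects)) {
    gg <- gg + ggplot2::geom_point(
      data = defects,
      ggplot2::aes(shape = factor(.data$charge)), colour = "white",
      size = 2.5) +
      ggplot2::scale_shape_manual(values = c("-0.5" = 17, "0.5" = 19),
                                  name = "charge")
    plus <- defects[defects$charge > 0 & !is.na(defects$ex), ]
    if (nrow(plus))
      gg <- gg + ggplot2::geom_segment(
        data = plus,
        ggplot2::aes(xend = .data$x + 2 * .data$ex,
                     yend = .data$y + 2 * .data$ey),
        colour = "white")
  }
  gg
}

#' Plot a flow field (vorticity heat map)
#'
#' @param object A [flow_field()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flow_field <- function(object, ...) {
  df <- field_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$omega)) +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x", y = "y", fill = "vorticity")
}

#' Plot 1D defect-hydrodynamics profiles
#'
#' @param object A `hydro_profiles` tibble from [steady_state_solve()].
#' @param ... Unused.
#' @return A ggplot object (faceted profiles).
#' @export
autoplot.hydro_profiles <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as.data.frame(object)[c("x", "alpha", "n", "rho", "p", "T3", "vn")],
    -"x", names_to = "field", values_to = "value")
  long$field <- factor(long$field,
                       levels = c("alpha", "n", "rho", "p", "T3", "vn"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~field, scales = "free_y") +
    ggplot2::labs(x = "x", y = NULL)
}

#' Plot defect world lines
#'
#' @param object A `defect_trajectories` object.
#' @param axis Projection axis ("x" or "y").
#' @param ... Unused.
#' @return A ggplot object: coordinate vs time world lines coloured by
#'   charge.
#' @export
autoplot.defect_trajectories <- function(object, axis = "x", ...) {
  df <- object$trajectories
  df$coord <- df[[axis]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coord, y = .data$time,
                                   group = .data$id,
                                   colour = factor(.data$charge))) +
    ggplot2::geom_path() +
    ggplot2::scale_colour_manual(values = c("-0.5" = "magenta",
                                            "0.5" = "darkgreen"),
                                 name = "charge") +
    ggplot2::labs(x = axis, y = "time")
}

#' Plot a dipole-moment time series
#'
#' @param object A `dipole_series` from [dipole_from_trajectories()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dipole_series <- function(object, ...) {
  ggplot2::ggplot(object$series, ggplot2::aes(x = .data$time, y = .data$D)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = object$mean, colour = "red") +
    ggplot2::labs(x = "time", y = "dipole moment D")
}
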