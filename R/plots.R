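#' Plot a flow field
#'
#' Speed map on the active cells with the geometry outline; the low-velocity
#' pocket hugging the carina shows up as the dark patch at the apex.
#'
#' @param object A `flow_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flow_field <- function(object, ...) {
  df <- tidy(object)
  out <- as.data.frame(object$mesh$geometry$outline)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x * 1e3, y = .data$y * 1e3)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$speed * 1e3)) +
    ggplot2::geom_path(data = rbind(out, out[1, ]),
                       ggplot2::aes(x = .data$x * 1e3, y = .data$y * 1e3),
                       inherit.aes = FALSE, linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(name = "speed [mm/s]") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]")
}

#' Plot stored trajectories of an ensemble
#'
#' @param object A `trajectory_ensemble` with stored paths
#'   (`tracking_control(store_paths = ...)`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trajectory_ensemble <- function(object, ...) {
  if (!nrow(object$paths))
    stop("no stored trajectories; re-run with store_paths > 0", call. = FALSE)
  out <- as.data.frame(object$geometry$outline)
  ggplot2::ggplot(object$paths,
                  ggplot2::aes(x = .data$x * 1e3, y = .data$y * 1e3,
                               group = .data$particle_id)) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.2) +
    ggplot2::geom_path(data = rbind(out, out[1, ]),
                       ggplot2::aes(x = .data$x * 1e3, y = .data$y * 1e3),
                       inherit.aes = FALSE, linewidth = 0.3, colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]")
}

#' Plot a carina sweep table
#'
#' Low-velocity area against the swept variable (angle or viscosity).
#'
#' @param object A `carina_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.carina_sweep <- function(object, ...) {
  by_angle <- length(unique(object$angle_deg)) > 1
  xvar <- if (by_angle) "angle_deg" else "viscosity"
  xlab <- if (by_angle) "opening angle [deg]" else "viscosity [Pa s]"
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[xvar]],
                                       y = .data$low_velocity_area * 1e12)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = expression("low-velocity area " * "[" * mu * m^2 * "]"))
}
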