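#' Tidy a flow field into a tibble of cell-centre samples
#'
#' @param x A `flow_field`.
#' @param ... Unused.
#' @return Tibble with `x`, `y`, `u`, `v`, `p`, `speed` on active cell centres.
#' @export
tidy.flow_field <- function(x, ...) {
  cc <- cell_centres(x$mesh)
  u <- 0.5 * (x$u[cbind(cc$i, cc$j)] + x$u[cbind(cc$i + 1L, cc$j)])
  v <- 0.5 * (x$v[cbind(cc$i, cc$j)] + x$v[cbind(cc$i, cc$j + 1L)])
  p <- x$p[cbind(cc$i, cc$j)]
  tibble::tibble(x = cc$x, y = cc$y, u = u, v = v, p = p,
                 speed = sqrt(u^2 + v^2))
}

#' One-row summary of a flow solve
#'
#' @param x A `flow_field`.
#' @param ... Unused.
#' @return Tibble with convergence, regime and conservation diagnostics.
#' @export
glance.flow_field <- function(x, ...) {
  tibble::tibble(
    converged = x$converged,
    steps = x$steps,
    residual = x$residual,
    channel_re = x$channel_reynolds %||% NA_real_,
    max_speed = max_speed(x),
    mean_inlet_speed = x$vbar,
    divergence_rms = divergence_norm(x),
    mass_error = mass_conservation_error(x),
    n_cells = x$mesh$n_active,
    cell_size = x$mesh$h
  )
}

#' Tidy a trajectory ensemble (one row per particle)
#'
#' @param x A `trajectory_ensemble`.
#' @param ... Unused.
#' @return The per-particle summary tibble.
#' @export
tidy.trajectory_ensemble <- function(x, ...) x$summary

#' One-row summary of a tracking run
#'
#' @param x A `trajectory_ensemble`.
#' @param ... Unused.
#' @return Tibble with census fractions, carina fraction, residence and
#'   particle-Reynolds diagnostics.
#' @export
glance.trajectory_ensemble <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n = x$n,
    dt = x$dt,
    frac_outlet_1 = mean(s$status == "exited_outlet_1"),
    frac_outlet_2 = mean(s$status == "exited_outlet_2"),
    frac_wall_contact = mean(s$status == "wall_contact"),
    frac_max_time = mean(s$status == "max_time"),
    carina_fraction = carina_fraction(x),
    mean_residence = mean_carina_residence(x),
    max_particle_re = max(s$max_re_p),
    region_radius = x$region_radius
  )
}
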