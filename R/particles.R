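#' Particle Reynolds number
#'
#' `Re_p = rho |v_s| D_p / mu`, built on the slip speed (fluid velocity at the
#' particle position minus particle velocity). `Re_p < 1` along a trajectory
#' justifies the near-Stokes Schiller-Naumann drag closure.
#'
#' @param fluid A [fluid_properties] object.
#' @param slip_speed Slip speed(s) `|v_s|` in m/s (vectorised, non-negative).
#' @param diameter Particle diameter in m.
#' @return Dimensionless particle Reynolds number(s).
#' @examples
#' particle_reynolds(medium("non_conditioned"), 3.66e-6, 14e-6)  # ~3.5e-5
#' @export
particle_reynolds <- function(fluid, slip_speed, diameter) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (any(slip_speed < 0)) stop("slip_speed must be non-negative", call. = FALSE)
  fluid$density * slip_speed * diameter / fluid$viscosity
}

#' Schiller-Naumann drag coefficient
#'
#' `C_d = 24 / Re_p * (1 + 0.15 Re_p^0.687)`, the standard correlation for
#' solid spheres at moderate particle Reynolds numbers. In the Stokes limit
#' `C_d * Re_p -> 24`.
#'
#' @param re_p Particle Reynolds number(s), strictly positive (the drag-force
#'   routine short-circuits the zero-slip case without evaluating `C_d`).
#' @return Dimensionless drag coefficient(s).
#' @examples
#' drag_coefficient(1)    # 27.6
#' drag_coefficient(0.1)  # ~247.4
#' @export
drag_coefficient <- function(re_p) {
  if (any(re_p <= 0)) stop("re_p must be strictly positive", call. = FALSE)
  24 / re_p * (1 + 0.15 * re_p^0.687)
}

#' Drag force on a sphere
#'
#' `F_d = 1/2 C_d rho A_p |v_s| v_s`: parallel to the slip velocity, i.e. it
#' drives the particle towards the local fluid velocity. Zero slip returns the
#' zero vector without evaluating the drag coefficient.
#'
#' @param particle A [particle_properties] object.
#' @param fluid A [fluid_properties] object.
#' @param slip_velocity Slip velocity vector `v_fluid - v_particle` (m/s).
#' @param schiller With `FALSE` the finite-Reynolds correction factor
#'   `1 + 0.15 Re_p^0.687` is dropped and the force reduces exactly to Stokes
#'   drag `3 pi mu D_p v_s`.
#' @return Force vector in N.
#' @export
drag_force <- function(particle, fluid, slip_velocity, schiller = TRUE) {
  stopifnot(inherits(particle, "particle_properties"),
            inherits(fluid, "fluid_properties"))
  s <- sqrt(sum(slip_velocity^2))
  if (s == 0) return(slip_velocity * 0)
  re_p <- particle_reynolds(fluid, s, particle$diameter)
  cd <- if (schiller) drag_coefficient(re_p) else 24 / re_p
  0.5 * cd * fluid$density * particle$area * s * slip_velocity
}

#' Gravity (and optionally buoyancy-corrected) force
#'
#' `F_g = m_p g`. With `buoyancy = TRUE` the displaced-fluid weight is
#' subtracted: `(rho_p - rho) V_p g`, which reduces to `m_p g` as the fluid
#' density goes to zero.
#'
#' @param particle A [particle_properties] object.
#' @param gravity Gravitational acceleration vector in m/s^2. The tracking
#'   default is a horizontally mounted device (gravity out of the flow plane,
#'   i.e. `c(0, 0)` in-plane); pass `c(0, -9.81)` for in-plane gravity.
#' @param fluid Optional [fluid_properties], required when `buoyancy = TRUE`.
#' @param buoyancy Subtract the displaced-fluid weight.
#' @return Force vector in N.
#' @examples
#' sqrt(sum(gravity_force(particle_properties(), c(0, -9.81))^2))  # ~1.48e-11 N
#' @export
gravity_force <- function(particle, gravity = c(0, -9.81), fluid = NULL,
                          buoyancy = FALSE) {
  stopifnot(inherits(particle, "particle_properties"))
  if (buoyancy) {
    stopifnot(inherits(fluid, "fluid_properties"))
    vol <- pi * particle$diameter^3 / 6
    (particle$density - fluid$density) * vol * gravity
  } else {
    particle$mass * gravity
  }
}

#' Particle momentum relaxation time
#'
#' `tau_p = rho_p D_p^2 / (18 mu)`: the Stokes-drag velocity relaxation time.
#' For the 14 um cell analogue in culture medium this is about 8 us, far below
#' any convective time scale - the stiffness that motivates the semi-analytic
#' drag integrator.
#'
#' @param particle A [particle_properties] object.
#' @param fluid A [fluid_properties] object.
#' @return Relaxation time in s.
#' @export
particle_relaxation_time <- function(particle, fluid) {
  stopifnot(inherits(particle, "particle_properties"),
            inherits(fluid, "fluid_properties"))
  particle$density * particle$diameter^2 / (18 * fluid$viscosity)
}

resolve_velocity_fn <- function(velocity) {
  if (inherits(velocity, "flow_field")) {
    field <- velocity
    function(x, y) {
      uv <- interp_velocity(field, x, y)
      c(uv$u[1], uv$v[1])
    }
  } else if (is.function(velocity)) {
    velocity
  } else {
    stop("velocity must be a flow_field or a function(x, y) -> c(u, v)",
         call. = FALSE)
  }
}

#' Advance one particle by one time step
#'
#' Semi-analytic update of `m_p dv/dt = F_d + F_g`: the fluid velocity is
#' sampled at the half-step position, the Schiller-Naumann factor is frozen
#' over the step, and the resulting linear drag equation is integrated
#' exactly. This reference implementation mirrors the compiled ensemble
#' tracker step for step.
#'
#' @param state List with `position` (m), `velocity` (m/s), `time` (s).
#' @param velocity A `flow_field` or a function `(x, y) -> c(u, v)`.
#' @param dt Time step in s (> 0).
#' @param particle,fluid Particle and fluid properties.
#' @param gravity In-plane gravitational acceleration vector (m/s^2); default
#'   zero (device mounted horizontally).
#' @param buoyancy Apply the buoyancy correction to gravity.
#' @param schiller Apply the finite-Reynolds drag correction.
#' @return The updated state; `$slip` holds the slip velocity used.
#' @export
step_particle <- function(state, velocity, dt, particle, fluid,
                          gravity = c(0, 0), buoyancy = FALSE,
                          schiller = TRUE) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  vf <- resolve_velocity_fn(velocity)
  tau_p <- particle_relaxation_time(particle, fluid)
  g_eff <- if (buoyancy) gravity * (1 - fluid$density / particle$density)
           else gravity
  x <- state$position; vp <- state$velocity
  xm <- x + 0.5 * dt * vp
  uf <- vf(xm[1], xm[2])
  slip <- uf - vp
  s <- sqrt(sum(slip^2))
  re_p <- particle_reynolds(fluid, s, particle$diameter)
  f <- if (schiller && re_p > 0) 1 + 0.15 * re_p^0.687 else 1
  tau <- tau_p / f
  E <- exp(-dt / tau)
  A <- uf + g_eff * tau
  v_new <- A + (vp - A) * E
  x_new <- x + A * dt + tau * (vp - A) * (1 - E)
  list(position = x_new, velocity = v_new, time = state$time + dt,
       slip = slip, re_p = re_p)
}

#' Tracking control settings
#'
#' @param dt Time step in s; `NULL` picks `cfl * h / max speed` from the field.
#' @param cfl Courant factor for the automatic time step.
#' @param max_time Trajectory time cap in s; particles still in flow are
#'   terminated with status `max_time`.
#' @param region_radius Carina-region radius in m used for the online
#'   residence-time accumulator (default 5 particle diameters, 70 um).
#' @param gravity In-plane gravity vector (m/s^2); default `c(0, 0)` for a
#'   horizontally mounted device.
#' @param buoyancy Apply the buoyancy correction to gravity.
#' @param schiller Apply the finite-Reynolds drag correction.
#' @param wall_clearance Wall-contact threshold in m; `NULL` means half a
#'   particle diameter.
#' @param wall_mode `"slide"` (default): wall contacts are impermeable - the
#'   particle is projected back to the clearance surface and its inward
#'   normal velocity dropped, with every contact counted; physically, on a
#'   smooth no-slip wall a drag-dominated particle grazes but does not stop.
#'   `"arrest"`: freeze on first contact (the literal arrest-candidate rule;
#'   on a staircase-masked grid this over-triggers along oblique walls).
#' @param store_paths Number of leading particles whose full trajectories are
#'   retained (for plotting / audits).
#' @param store_every Thinning factor for stored trajectories.
#' @return A `tracking_control` list.
#' @export
tracking_control <- function(dt = NULL, cfl = 0.5, max_time = 20,
                             region_radius = 5 * 14e-6, gravity = c(0, 0),
                             buoyancy = FALSE, schiller = TRUE,
                             wall_clearance = NULL,
                             wall_mode = c("slide", "arrest"),
                             store_paths = 0L, store_every = 5L) {
  wall_mode <- match.arg(wall_mode)
  structure(list(dt = dt, cfl = cfl, max_time = max_time,
                 region_radius = region_radius, gravity = gravity,
                 buoyancy = buoyancy, schiller = schiller,
                 wall_clearance = wall_clearance, wall_mode = wall_mode,
                 store_paths = as.integer(store_paths),
                 store_every = as.integer(store_every)),
            class = "tracking_control")
}

STATUS_LEVELS <- c("exited_outlet_1", "exited_outlet_2", "wall_contact",
                   "max_time", "error_outside")

#' Track an ensemble of particles through a flow field
#'
#' One-way-coupled Lagrangian tracking: every seeded particle is advanced
#' under Schiller-Naumann drag and (optional, buoyancy-corrected) gravity
#' until it exits an outlet, comes within half a diameter of a wall
#' (`wall_contact`, the arrest surrogate - adhesion itself is biology and out
#' of scope), or times out. Particles start at the local fluid velocity.
#'
#' Per trajectory the tracker records the terminal status, the exact minimum
#' distance of the stepped path to the carina apex, the time spent inside the
#' carina region (segment-disc clipping, not sample counting), and the
#' maximum particle Reynolds number encountered.
#'
#' @param seeds Tibble/data frame with seed columns `x`, `y` (m), e.g. from
#'   [seed_inlet()].
#' @param field A converged `flow_field`.
#' @param particle A [particle_properties] object.
#' @param fluid A [fluid_properties] object (normally the one the field was
#'   solved with).
#' @param control A [tracking_control] object.
#' @return A `trajectory_ensemble`: `$summary` (one row per particle),
#'   `$census` (counts per terminal status), `$paths` (stored trajectories),
#'   and the tracking parameters.
#' @export
track_particles <- function(seeds, field, particle, fluid,
                            control = tracking_control()) {
  stopifnot(inherits(field, "flow_field"),
            inherits(particle, "particle_properties"),
            inherits(fluid, "fluid_properties"))
  seeds <- tibble::as_tibble(seeds)
  if (!all(c("x", "y") %in% names(seeds)))
    stop("seeds must have columns x and y", call. = FALSE)
  n <- nrow(seeds)
  if (n < 1L) stop("no seeds supplied", call. = FALSE)
  m <- field$mesh
  geo <- m$geometry

  dt <- control$dt %||% (control$cfl * m$h / max(max_speed(field), field$vbar))
  clearance <- control$wall_clearance %||% (particle$diameter / 2)
  tau_p <- particle_relaxation_time(particle, fluid)
  repc <- fluid$density * particle$diameter / fluid$viscosity
  g_eff <- if (control$buoyancy)
    control$gravity * (1 - fluid$density / particle$density)
  else control$gravity

  outs <- geo$outlets
  omat <- do.call(rbind, lapply(outs, function(o)
    c(o$origin[1], o$origin[2], o$direction[1], o$direction[2], o$distance)))
  apex <- geo$apex

  store_id <- integer(n)
  ns <- min(control$store_paths, n)
  if (ns > 0) store_id[seq_len(ns)] <- seq_len(ns)

  tr <- cpp_track(seeds$x, seeds$y, field$u, field$v, m$dist,
                  m$x0, m$y0, m$h,
                  tau_p, repc, isTRUE(control$schiller),
                  g_eff[1], g_eff[2],
                  dt, control$max_time, clearance,
                  apex[1], apex[2], control$region_radius,
                  omat, store_id, control$store_every,
                  if (control$wall_mode == "arrest") 1L else 0L,
                  !is.null(field$zoom),
                  if (!is.null(field$zoom)) field$zoom$u else matrix(0, 1, 1),
                  if (!is.null(field$zoom)) field$zoom$v else matrix(0, 1, 1),
                  if (!is.null(field$zoom)) field$zoom$mesh$dist else matrix(0, 1, 1),
                  if (!is.null(field$zoom)) field$zoom$mesh$x0 else 0,
                  if (!is.null(field$zoom)) field$zoom$mesh$y0 else 0,
                  if (!is.null(field$zoom)) field$zoom$mesh$h else 1,
                  if (!is.null(field$zoom)) field$zoom$box else numeric(4))

  status <- factor(STATUS_LEVELS[tr$status], levels = STATUS_LEVELS)
  summary <- tibble::tibble(
    particle_id = seq_len(n),
    x0 = seeds$x, y0 = seeds$y,
    status = status,
    x_end = tr$x_end, y_end = tr$y_end,
    exit_time = tr$exit_time,
    min_dist_apex = tr$min_dist_apex,
    residence_time = tr$residence,
    max_re_p = tr$max_rep,
    n_steps = tr$n_steps,
    n_wall_touch = tr$n_wall_touch,
    touch_in_region = tr$touch_in_region
  )
  census <- dplyr::count(summary, .data$status, .drop = FALSE, name = "n")

  structure(list(
    summary = summary,
    census = census,
    paths = tibble::as_tibble(tr$path),
    n = n, dt = dt,
    region_radius = control$region_radius,
    particle = particle, fluid = fluid,
    seeding = attr(seeds, "seeding", exact = TRUE),
    control = control,
    geometry = geo
  ), class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %d particles, dt = %.3g s\n", x$n, x$dt))
  print(x$census)
  cat(sprintf("  max particle Re: %.3g; carina fraction (r = %g um): %.4g\n",
              max(x$summary$max_re_p), x$region_radius * 1e6,
              carina_fraction(x)))
  invisible(x)
}
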