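#' Solver control settings
#'
#' @param tol Convergence monitor on the steady residual (normalised maximum
#'   velocity change per convective time unit); 1e-5 by default.
#' @param max_steps Cap on pseudo-time steps at the finest level.
#' @param cfl Courant safety factor for the pseudo-time step.
#' @param check_every Steps between residual evaluations.
#' @param continuation Warm-start each mesh from a coarsened solve (strongly
#'   recommended; cuts fine-grid iterations several-fold).
#' @param verbose Print residuals while marching.
#' @return A `solver_control` list.
#' @export
solver_control <- function(tol = 1e-5, max_steps = 2e5, cfl = 0.35,
                           check_every = 25L, continuation = TRUE,
                           verbose = FALSE) {
  structure(list(tol = tol, max_steps = max_steps, cfl = cfl,
                 check_every = as.integer(check_every),
                 continuation = continuation, verbose = verbose),
            class = "solver_control")
}

# mean (bulk) velocity of the 3-D semicircular duct; the 2-D mid-plane model
# is run at the same mean velocity so Reynolds number and velocity scale match
bulk_velocity <- function(geometry, bc) {
  area <- cross_section("semicircle", diameter = geometry$calibre)$area
  bc$flow_rate / area
}

# Dirichlet inlet profile on the active inlet faces, normalised so the
# discrete inlet flux equals vbar * w exactly.
inlet_profile_values <- function(mesh, bc, vbar) {
  w <- mesh$geometry$calibre
  idx <- which(mesh$uType == FACE_INLET)
  jj <- ((idx - 1L) %/% (mesh$nx + 1L)) + 1L
  y <- mesh$y0 + (jj - 0.5) * mesh$h
  prof <- if (bc$inlet_profile == "parabolic") {
    1.5 * vbar * pmax(0, 1 - (2 * y / w)^2)
  } else {
    rep(vbar, length(y))
  }
  target <- vbar * w
  prof <- prof * target / (sum(prof) * mesh$h)
  list(idx = idx, values = prof)
}

#' Solve the steady incompressible laminar flow in a meshed geometry
#'
#' Integrates the incompressible Navier-Stokes equations
#' (continuity \eqn{\nabla \cdot v = 0}; momentum
#' \eqn{\rho (v \cdot \nabla) v = -\nabla p + \mu \Delta v})
#' to steady state on the masked MAC grid: central differencing for convection
#' and diffusion, incremental pressure projection each pseudo-time step with a
#' prefactored sparse Cholesky (CHOLMOD) Poisson solve. The inlet carries a
#' fully developed (or uniform) profile at the bulk velocity `Q / A` of the
#' semicircular duct; outlets are zero-pressure; walls are no-slip.
#'
#' The configuration Reynolds number must stay below 500 (the scheme is built
#' for the laminar regime; the target flows sit below 100).
#'
#' @param mesh A [generate_mesh()] result.
#' @param fluid A [fluid_properties] object.
#' @param bc A [boundary_conditions] object.
#' @param control A [solver_control] object.
#' @return A `flow_field` object: staggered velocity arrays, pressure (Pa),
#'   residual history (tibble), `converged` flag and diagnostics.
#' @export
solve_steady_flow <- function(mesh, fluid, bc, control = solver_control()) {
  stopifnot(inherits(mesh, "flow_mesh"), inherits(fluid, "fluid_properties"),
            inherits(bc, "boundary_conditions"))
  geo <- mesh$geometry
  re <- channel_reynolds(fluid, bc,
                         cross_section("semicircle", diameter = geo$calibre))
  if (re >= 500)
    stop(sprintf("configuration Reynolds number %.1f exceeds the laminar-regime ",
                 re), "guard (500)", call. = FALSE)

  vbar <- bulk_velocity(geo, bc)
  nu <- fluid$viscosity / fluid$density
  w <- geo$calibre

  init <- NULL
  if (isTRUE(control$continuation) && mesh$n_across >= 24L) {
    coarse_mesh <- generate_mesh(geo, target_cell_size = 2 * mesh$h,
                                 wall_layers = mesh$wall_layers)
    coarse <- solve_steady_flow(coarse_mesh, fluid, bc, control)
    init <- coarse
  }

  field <- march_to_steady(mesh, fluid, bc, control, vbar, nu, init)
  field$channel_reynolds <- re
  field
}

# interpolate a (possibly coarser) solved field onto this mesh's staggered nodes
prolong_field <- function(mesh, from) {
  fm <- from$mesh
  nx <- mesh$nx; ny <- mesh$ny; h <- mesh$h
  ux <- mesh$x0 + (seq_len(nx + 1L) - 1L) * h
  uy <- mesh$y0 + (seq_len(ny) - 0.5) * h
  gu <- cpp_interp_velocity(rep(ux, times = ny), rep(uy, each = nx + 1L),
                            from$u, from$v, fm$x0, fm$y0, fm$h)
  u <- matrix(gu[, 1], nx + 1L, ny)
  vx <- mesh$x0 + (seq_len(nx) - 0.5) * h
  vy <- mesh$y0 + (seq_len(ny + 1L) - 1L) * h
  gv <- cpp_interp_velocity(rep(vx, times = ny + 1L), rep(vy, each = nx),
                            from$u, from$v, fm$x0, fm$y0, fm$h)
  v <- matrix(gv[, 2], nx, ny + 1L)
  cx <- mesh$x0 + (seq_len(nx) - 0.5) * h
  cy <- mesh$y0 + (seq_len(ny) - 0.5) * h
  qv <- cpp_interp_cellfield(rep(cx, times = ny), rep(cy, each = nx),
                             from$p / from$fluid$density, fm$x0, fm$y0, fm$h)
  q <- matrix(qv, nx, ny)
  list(u = u, v = v, q = q)
}

march_to_steady <- function(mesh, fluid, bc, control, vbar, nu, init = NULL) {
  nx <- mesh$nx; ny <- mesh$ny; h <- mesh$h
  if (is.null(init)) {
    u <- matrix(0, nx + 1L, ny); v <- matrix(0, nx, ny + 1L)
    q <- matrix(0, nx, ny)
  } else {
    pf <- prolong_field(mesh, init)
    u <- pf$u; v <- pf$v; q <- pf$q
    u[mesh$uType == FACE_EXTERNAL | mesh$uType == FACE_WALL] <- 0
    v[mesh$vType == FACE_EXTERNAL | mesh$vType == FACE_WALL] <- 0
    q[!mesh$active] <- 0
  }
  inlet <- inlet_profile_values(mesh, bc, vbar)
  u[inlet$idx] <- inlet$values

  ch <- poisson_factor(mesh)
  actIdx <- which(mesh$active)
  tscale <- w_scale <- mesh$geometry$calibre
  accel_scale <- vbar^2 / w_scale

  umax <- max(abs(u), abs(v), vbar)
  new_dt <- function(umax) {
    min(control$cfl * h / umax, 0.25 * h^2 / nu, 1.6 * nu / umax^2)
  }
  dt <- new_dt(umax)

  hist_step <- integer(0); hist_res <- numeric(0); hist_div <- numeric(0)
  u_prev <- u
  converged <- FALSE
  step <- 0L
  divn <- NA_real_
  res <- Inf
  while (step < control$max_steps) {
    step <- step + 1L
    pr <- cpp_predict(u, v, q, mesh$uType, mesh$vType, mesh$uSign, mesh$vSign,
                      mesh$cellIdx, mesh$n_active, h, dt, nu, TRUE)
    phi <- as.numeric(Matrix::solve(ch, -pr$div * h^2 / dt))
    cpp_correct(pr$us, pr$vs, phi, mesh$uType, mesh$vType, mesh$uSign,
                mesh$vSign, mesh$cellIdx, h, dt)
    u <- pr$us; v <- pr$vs
    u[inlet$idx] <- inlet$values
    q[actIdx] <- q[actIdx] + phi

    if (step %% control$check_every == 0L) {
      res <- max(abs(u - u_prev)) / (control$check_every * dt) / accel_scale
      u_prev <- u
      hist_step <- c(hist_step, step); hist_res <- c(hist_res, res)
      if (control$verbose)
        message(sprintf("  step %6d  dt %.3g  res %.3e", step, dt, res))
      if (res <= control$tol) { converged <- TRUE; break }
      umax <- max(abs(u), abs(v), vbar)
      dt <- new_dt(umax)
    }
  }
  if (!converged)
    warning(sprintf(paste0("flow solver stopped at %d steps with residual ",
                           "%.3g > tol %.3g"), step, res, control$tol),
            call. = FALSE)

  structure(list(
    mesh = mesh, fluid = fluid, bc = bc,
    u = u, v = v, p = fluid$density * q,
    vbar = vbar, q2d = vbar * mesh$geometry$calibre,
    converged = converged, steps = step, residual = res,
    residuals = tibble::tibble(step = hist_step, residual = hist_res),
    control = control
  ), class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "<flow_field> %s, Re = %.3g, %s after %d steps (residual %.2e)\n",
    x$fluid$label, x$channel_reynolds %||% NA,
    if (x$converged) "converged" else "NOT converged", x$steps, x$residual))
  cat(sprintf("  max speed %.4g m/s, divergence RMS %.3g 1/s, mass error %.3g%%\n",
              max_speed(x), divergence_norm(x), 100 * mass_conservation_error(x)))
  invisible(x)
}

#' Interpolate the velocity field at arbitrary points
#'
#' Component-wise bilinear interpolation on the staggered grid (the same
#' interpolant the particle tracker uses). When the field carries a carina
#' refinement patch ([solve_carina_zoom()]), points inside the patch are
#' sampled from the fine grid.
#'
#' @param field A `flow_field`.
#' @param x,y Coordinates in m (vectorised).
#' @return A tibble with columns `x`, `y`, `u`, `v`, `speed`.
#' @export
interp_velocity <- function(field, x, y) {
  m <- field$mesh
  x <- as.numeric(x); y <- as.numeric(y)
  uv <- cpp_interp_velocity(x, y, field$u, field$v, m$x0, m$y0, m$h)
  if (!is.null(field$zoom)) {
    b <- field$zoom$box
    zin <- x > b[1] & x < b[2] & y > b[3] & y < b[4]
    if (any(zin)) {
      zm <- field$zoom$mesh
      uvz <- cpp_interp_velocity(x[zin], y[zin], field$zoom$u, field$zoom$v,
                                 zm$x0, zm$y0, zm$h)
      uv[zin, ] <- uvz
    }
  }
  tibble::tibble(x = x, y = y, u = uv[, 1], v = uv[, 2],
                 speed = sqrt(uv[, 1]^2 + uv[, 2]^2))
}

#' Discrete divergence norm of a flow field
#'
#' Root-mean-square of the cell-wise discrete divergence over active cells,
#' in 1/s. Machine-zero for any exactly divergence-free staggered field and
#' bounded by the projection accuracy for solver output.
#'
#' @param field A `flow_field`.
#' @return Scalar RMS divergence (1/s).
#' @export
divergence_norm <- function(field) {
  m <- field$mesh
  d <- cell_divergence(field)
  sqrt(mean(d^2))
}

cell_divergence <- function(field) {
  m <- field$mesh
  nx <- m$nx; ny <- m$ny; h <- m$h
  du <- (field$u[2:(nx + 1), , drop = FALSE] -
           field$u[1:nx, , drop = FALSE]) / h
  dv <- (field$v[, 2:(ny + 1), drop = FALSE] -
           field$v[, 1:ny, drop = FALSE]) / h
  (du + dv)[m$active]
}

#' Volumetric flux through a tagged boundary
#'
#' Signed, outward positive, per unit depth (m^2/s). The inlet therefore
#' reports `-Q_2D`, and the tagged fluxes sum to zero for a mass-conserving
#' solution.
#'
#' @param field A `flow_field`.
#' @param boundary_tag One of `"inlet"`, `"outlet_1"`, `"outlet_2"`, `"wall"`.
#' @return Scalar flux in m^2/s.
#' @export
flux_through <- function(field, boundary_tag) {
  codes <- c(inlet = FACE_INLET, outlet_1 = FACE_OUTLET1,
             outlet_2 = FACE_OUTLET2, wall = FACE_WALL)
  if (!boundary_tag %in% names(codes))
    stop(sprintf("unknown boundary tag '%s'", boundary_tag), call. = FALSE)
  code <- codes[[boundary_tag]]
  m <- field$mesh
  nx <- m$nx; ny <- m$ny
  tot <- 0
  idx <- which(m$uType == code)
  if (length(idx)) {
    ii <- ((idx - 1L) %% (nx + 1L)) + 1L
    jj <- ((idx - 1L) %/% (nx + 1L)) + 1L
    westAct <- ii > 1L & m$active[cbind(pmax(ii - 1L, 1L), jj)]
    sgn <- ifelse(westAct, 1, -1)     # outward = away from the active cell
    tot <- tot + sum(sgn * field$u[idx]) * m$h
  }
  idx <- which(m$vType == code)
  if (length(idx)) {
    ii <- ((idx - 1L) %% nx) + 1L
    jj <- ((idx - 1L) %/% nx) + 1L
    southAct <- jj > 1L & m$active[cbind(ii, pmax(jj - 1L, 1L))]
    sgn <- ifelse(southAct, 1, -1)
    tot <- tot + sum(sgn * field$v[idx]) * m$h
  }
  tot
}

#' Relative global mass-conservation error
#'
#' @param field A `flow_field`.
#' @return `|sum of boundary fluxes| / Q_2D` (dimensionless).
#' @export
mass_conservation_error <- function(field) {
  s <- flux_through(field, "inlet") + flux_through(field, "outlet_1") +
    (if (!is.null(field$mesh$geometry$outlets$outlet_2))
       flux_through(field, "outlet_2") else 0)
  abs(s) / field$q2d
}

#' Maximum flow speed (convergence control variable)
#'
#' Maximum velocity magnitude over active cell centres.
#'
#' @param field A `flow_field`.
#' @return Scalar speed in m/s.
#' @export
max_speed <- function(field) {
  m <- field$mesh
  nx <- m$nx; ny <- m$ny
  uc <- 0.5 * (field$u[1:nx, , drop = FALSE] + field$u[2:(nx + 1), , drop = FALSE])
  vc <- 0.5 * (field$v[, 1:ny, drop = FALSE] + field$v[, 2:(ny + 1), drop = FALSE])
  sp <- sqrt(uc^2 + vc^2)
  max(sp[m$active])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
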