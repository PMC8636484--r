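#' Seed particle positions across the inlet
#'
#' Places `n` seeds on a plane a short way downstream of the inlet (5% of the
#' parent length, so interpolation is clear of the inlet faces), distributed
#' across the channel width minus a wall margin. Reproducible for a fixed
#' `rng_seed`; the generator state of the session is left untouched.
#'
#' @param geometry A [bifurcation_geometry].
#' @param n Number of seeds.
#' @param distribution `"uniform"` (throughout the cross-section, the default
#'   release condition), `"flow_weighted"` (density proportional to the local
#'   parabolic flux), or `"centreline"` (all on the axis).
#' @param rng_seed Integer seed.
#' @param margin Minimum distance from the walls in m (default half a cell
#'   diameter, 7 um).
#' @return A tibble with columns `x`, `y` and a `seeding` attribute recording
#'   the seeding specification used.
#' @export
seed_inlet <- function(geometry, n, distribution = c("uniform", "flow_weighted",
                                                     "centreline"),
                       rng_seed = 1L, margin = 7e-6) {
  distribution <- match.arg(distribution)
  stopifnot(inherits(geometry, "bifurcation_geometry"))
  if (n < 1L) stop("n must be at least 1", call. = FALSE)
  w <- geometry$calibre
  if (margin >= w / 2)
    stop("seeding margin must be smaller than the channel half-width",
         call. = FALSE)
  half <- w / 2 - margin
  x_seed <- geometry$inlet$x + 0.05 * geometry$parent_length

  y <- switch(distribution,
    centreline = rep(0, n),
    uniform = with_preserved_seed(rng_seed, stats::runif(n, -half, half)),
    flow_weighted = with_preserved_seed(rng_seed, {
      # rejection sampling against the parabolic flux profile
      out <- numeric(0)
      while (length(out) < n) {
        cand <- stats::runif(2L * (n - length(out)), -half, half)
        keep <- stats::runif(length(cand)) < (1 - (2 * cand / w)^2)
        out <- c(out, cand[keep])
      }
      out[seq_len(n)]
    })
  )
  res <- tibble::tibble(x = rep(x_seed, n), y = y)
  attr(res, "seeding") <- list(n = n, distribution = distribution,
                               rng_seed = rng_seed, margin = margin,
                               x = x_seed)
  res
}

# evaluate expr under a fixed seed without disturbing the session RNG state
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Plane-Poiseuille velocity profile (analytic oracle)
#'
#' `u(y) = 1.5 * mean_speed * (1 - (2 y / width)^2)`: the exact steady laminar
#' solution in a straight 2-D channel, used to validate the flow solver.
#'
#' @param width Channel width in m.
#' @param mean_speed Bulk (mean) speed in m/s.
#' @param y Transverse coordinate(s) in m, `|y| <= width / 2`.
#' @return Speed(s) in m/s.
#' @export
poiseuille_profile <- function(width, mean_speed, y) {
  if (any(abs(y) > width / 2 + 1e-15))
    stop("coordinate outside the channel", call. = FALSE)
  1.5 * mean_speed * (1 - (2 * y / width)^2)
}

#' Stokes terminal settling velocity (analytic oracle)
#'
#' `(rho_p - rho) g D_p^2 / (18 mu)`: terminal speed of a small sphere under
#' gravity, buoyancy and Stokes drag. About 3.66 um/s for the cell analogue in
#' non-conditioned medium - negligible against mm/s flow speeds, which is why
#' in-plane gravity hardly bends the trajectories.
#'
#' @param particle A [particle_properties] object.
#' @param fluid A [fluid_properties] object.
#' @param g Gravitational acceleration magnitude, m/s^2.
#' @return Settling speed in m/s (positive = denser than the fluid).
#' @export
stokes_settling_velocity <- function(particle, fluid, g = 9.81) {
  (particle$density - fluid$density) * g * particle$diameter^2 /
    (18 * fluid$viscosity)
}

#' Exponential velocity-relaxation oracle
#'
#' Closed-form solution `u + (v0 - u) exp(-t / tau)` of the linear-drag
#' particle equation in a uniform stream; the integrator test reference.
#'
#' @param v0 Initial particle velocity (m/s).
#' @param u Fluid velocity (m/s).
#' @param tau Relaxation time in s (> 0).
#' @param t Time(s) in s.
#' @return Velocity at time `t`.
#' @export
relaxation_oracle <- function(v0, u, tau, t) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  u + (v0 - u) * exp(-t / tau)
}

#' Build a flow field from an analytic velocity function
#'
#' Samples `fn(x, y) -> c(u, v)` on the staggered nodes of a mesh and wraps
#' the result as a `flow_field`, so analytic reference flows (uniform
#' advection, Poiseuille, linear straining) can be fed to everything that
#' consumes solver output.
#'
#' @param mesh A [generate_mesh()] result.
#' @param fn Function of `(x, y)` returning `c(u, v)` in m/s.
#' @param fluid Optional [fluid_properties] attached to the field.
#' @param vbar Velocity scale recorded on the field (used by default time
#'   stepping); default the maximum sampled speed.
#' @return A `flow_field` (pressure identically zero, `converged = TRUE`).
#' @export
synthetic_field <- function(mesh, fn, fluid = medium("non_conditioned"),
                            vbar = NULL) {
  stopifnot(inherits(mesh, "flow_mesh"))
  nx <- mesh$nx; ny <- mesh$ny; h <- mesh$h
  u <- matrix(0, nx + 1L, ny)
  for (j in seq_len(ny)) {
    yy <- mesh$y0 + (j - 0.5) * h
    for (i in seq_len(nx + 1L)) {
      u[i, j] <- fn(mesh$x0 + (i - 1L) * h, yy)[1]
    }
  }
  v <- matrix(0, nx, ny + 1L)
  for (j in seq_len(ny + 1L)) {
    yy <- mesh$y0 + (j - 1L) * h
    for (i in seq_len(nx)) {
      v[i, j] <- fn(mesh$x0 + (i - 0.5) * h, yy)[2]
    }
  }
  vb <- vbar %||% max(sqrt(u^2)[!is.na(u)], na.rm = TRUE)
  structure(list(
    mesh = mesh, fluid = fluid,
    bc = boundary_conditions(),
    u = u, v = v, p = matrix(0, nx, ny),
    vbar = max(vb, 1e-12), q2d = max(vb, 1e-12) * mesh$geometry$calibre,
    converged = TRUE, steps = 0L, residual = 0,
    residuals = tibble::tibble(step = integer(0), residual = numeric(0)),
    control = solver_control()
  ), class = "flow_field")
}
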