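fl <- medium("non_conditioned")
pp <- particle_properties()

test_that("particle property derivations and dimensionless numbers", {
  expect_equal(pp$mass, 1050 * pi * (14e-6)^3 / 6, tolerance = 1e-12)
  expect_equal(pp$mass, 1.509e-12, tolerance = 1e-3)
  expect_equal(pp$area, pi * (14e-6)^2 / 4, tolerance = 1e-12)
  # Re_p at the Stokes settling speed
  expect_equal(particle_reynolds(fl, 3.66e-6, 14e-6), 3.5e-5,
               tolerance = 2e-2)
  expect_equal(particle_reynolds(fl, 0, 14e-6), 0)
  expect_error(particle_reynolds(fl, -1, 14e-6), "non-negative")
})

test_that("Schiller-Naumann drag coefficient matches direct evaluation", {
  expect_equal(drag_coefficient(1), 24 * 1.15)
  expect_equal(drag_coefficient(0.1), 240 * (1 + 0.15 * 0.1^0.687))
  expect_equal(drag_coefficient(0.1), 247.4, tolerance = 1e-3)
  # Stokes limit: C_d * Re_p -> 24 (correction 0.15 Re^0.687 vanishes)
  re <- 10^seq(-8, -4)
  expect_equal(drag_coefficient(re) * re, rep(24, length(re)),
               tolerance = 1e-3)
  expect_error(drag_coefficient(0), "strictly positive")
})

test_that("drag force: zero slip, Stokes oracle, near-linearity", {
  expect_identical(drag_force(pp, fl, c(0, 0)), c(0, 0))
  # Stokes-regime magnitude against 3 pi mu D v
  vs <- c(1e-4, 0)
  fd <- drag_force(pp, fl, vs)
  stokes <- 3 * pi * fl$viscosity * pp$diameter * 1e-4
  expect_equal(sqrt(sum(fd^2)), stokes, tolerance = 5e-3)
  expect_equal(stokes, 1.93e-11, tolerance = 2e-3)
  # force is parallel to the slip velocity
  vs2 <- c(3e-5, -4e-5)
  fd2 <- drag_force(pp, fl, vs2)
  expect_equal(fd2[1] / fd2[2], vs2[1] / vs2[2], tolerance = 1e-12)
  # doubling slip doubles the force up to the finite-Re_p correction
  f1 <- sqrt(sum(drag_force(pp, fl, c(1e-5, 0))^2))
  f2 <- sqrt(sum(drag_force(pp, fl, c(2e-5, 0))^2))
  expect_equal(f2 / f1, 2, tolerance = 1e-3)
  # with the correction disabled, exact Stokes linearity
  expect_equal(sqrt(sum(drag_force(pp, fl, vs, schiller = FALSE)^2)),
               stokes, tolerance = 1e-12)
})

test_that("gravity force, buoyancy variant and relaxation time", {
  g <- c(0, -9.81)
  expect_equal(sqrt(sum(gravity_force(pp, g)^2)), 1.48e-11, tolerance = 2e-3)
  expect_identical(gravity_force(pp, c(0, 0)), c(0, 0))
  fb <- gravity_force(pp, g, fluid = fl, buoyancy = TRUE)
  vol <- pi * pp$diameter^3 / 6
  expect_equal(fb, (1050 - 1000) * vol * g, tolerance = 1e-12)
  # buoyancy correction reduces to m g as fluid density -> 0
  f0 <- gravity_force(pp, g, fluid = fluid_properties(1e-9, 1e-3),
                      buoyancy = TRUE)
  expect_equal(f0, gravity_force(pp, g), tolerance = 1e-9)
  tau <- particle_relaxation_time(pp, fl)
  expect_equal(tau, 7.8e-6, tolerance = 5e-3)
  expect_equal(particle_relaxation_time(pp, fluid_properties(1000, 2 * 1.46e-3)),
               tau / 2, tolerance = 1e-12)
  # tau g (1 - rho/rho_p) equals the Stokes settling speed
  expect_equal(tau * 9.81 * (1 - 1000 / 1050),
               stokes_settling_velocity(pp, fl), tolerance = 1e-12)
})

test_that("integrator matches the exponential relaxation oracle in uniform flow", {
  tau <- particle_relaxation_time(pp, fl)
  u <- c(0.02, 0)
  vf <- function(x, y) u
  st <- list(position = c(0, 0), velocity = c(0, 0), time = 0)
  dt <- tau / 10
  for (i in 1:30) st <- step_particle(st, vf, dt, pp, fl, schiller = FALSE)
  expect_equal(st$velocity[1], relaxation_oracle(0, u[1], tau, st$time),
               tolerance = 1e-3)
  # zero flow, zero gravity: particle stays put
  st0 <- step_particle(list(position = c(1e-3, 1e-3), velocity = c(0, 0),
                            time = 0), function(x, y) c(0, 0), 1e-3, pp, fl)
  expect_equal(st0$position, c(1e-3, 1e-3))
  expect_equal(st0$velocity, c(0, 0))
})

test_that("still fluid with in-plane gravity reaches the Stokes settling velocity", {
  vset <- stokes_settling_velocity(pp, fl)
  st <- list(position = c(0, 0), velocity = c(0, 0), time = 0)
  for (i in 1:60)
    st <- step_particle(st, function(x, y) c(0, 0), 1e-5, pp, fl,
                        gravity = c(0, -9.81), buoyancy = TRUE)
  expect_equal(-st$velocity[2], vset, tolerance = 0.01)
  expect_equal(vset, 3.66e-6, tolerance = 2e-3)
})

test_that("integrator converges at second order in a straining field", {
  # linear straining flow u = (kx, -ky): curved pathlines, no closed form
  # needed - a fine-dt run serves as reference
  k <- 50
  vf <- function(x, y) c(k * x, -k * y)
  run <- function(dt) {
    st <- list(position = c(1e-3, 1e-3), velocity = vf(1e-3, 1e-3), time = 0)
    while (st$time < 0.02 - dt / 2) st <- step_particle(st, vf, dt, pp, fl)
    st$position
  }
  ref <- run(6.25e-6)
  e1 <- sqrt(sum((run(1e-4) - ref)^2))
  e2 <- sqrt(sum((run(5e-5) - ref)^2))
  expect_gt(e1 / e2, 3)   # at least the nominal order 2 (ratio ~4)
  expect_lt(e1 / e2, 16)
})

test_that("ensemble census is conserved and tracking is deterministic", {
  ff <- ref_field()
  geo <- ff$mesh$geometry
  seeds <- seed_inlet(geo, 400L, rng_seed = 7L)
  ctl <- tracking_control(max_time = 30)
  e1 <- track_particles(seeds, ff, pp, fl, ctl)
  expect_equal(sum(e1$census$n), 400L)
  expect_setequal(levels(e1$summary$status),
                  c("exited_outlet_1", "exited_outlet_2", "wall_contact",
                    "max_time", "error_outside"))
  # identical seeds and config give a bit-identical ensemble
  e2 <- track_particles(seed_inlet(geo, 400L, rng_seed = 7L), ff, pp, fl, ctl)
  expect_identical(e1$summary, e2$summary)
  # time advances strictly along stored paths
  e3 <- track_particles(seeds[1:5, ], ff, pp, fl,
                        tracking_control(max_time = 30, store_paths = 5,
                                         store_every = 1))
  for (id in unique(e3$paths$particle_id)) {
    tt <- e3$paths$t[e3$paths$particle_id == id]
    expect_true(all(diff(tt) > 0))
  }
})

test_that("a centreline particle runs into the carina stagnation region", {
  ff <- ref_field()
  geo <- ff$mesh$geometry
  seeds <- seed_inlet(geo, 1L, distribution = "centreline")
  ens <- track_particles(seeds, ff, pp, fl, tracking_control(max_time = 30))
  expect_lt(ens$summary$min_dist_apex[1], 5 * pp$diameter)
  expect_equal(carina_fraction(ens), 1)
})

test_that("the compiled tracker agrees with the reference R stepper", {
  ff <- ref_channel()
  seeds <- tibble::tibble(x = 1e-3, y = 0.3e-3)
  ctl <- tracking_control(dt = 2e-4, max_time = 0.05, store_paths = 1,
                          store_every = 1)
  ens <- track_particles(seeds, ff, pp, fl, ctl)
  st <- list(position = c(seeds$x, seeds$y),
             velocity = unlist(interp_velocity(ff, seeds$x, seeds$y)[, c("u", "v")],
                               use.names = FALSE),
             time = 0)
  for (i in 1:20) st <- step_particle(st, ff, 2e-4, pp, fl)
  row <- ens$paths[ens$paths$t > st$time - 1e-9 & ens$paths$t < st$time + 1e-9, ]
  expect_equal(c(row$x, row$y), st$position, tolerance = 1e-12)
})
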