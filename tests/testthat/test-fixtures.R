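test_that("inlet seeding is reproducible, bounded and well distributed", {
  geo <- bifurcation_geometry(90)
  s1 <- seed_inlet(geo, 20000L, rng_seed = 1L)
  s2 <- seed_inlet(geo, 20000L, rng_seed = 1L)
  expect_identical(s1, s2)
  expect_false(identical(s1$y, seed_inlet(geo, 20000L, rng_seed = 2L)$y))
  half <- geo$calibre / 2 - 7e-6
  expect_true(all(abs(s1$y) <= half))
  # n = 1e5 uniform sample mean within 3 standard errors of the centre
  s <- seed_inlet(geo, 100000L, rng_seed = 3L)
  se <- (2 * half) / sqrt(12) / sqrt(100000)
  expect_lt(abs(mean(s$y)), 3 * se)
  # centreline
  expect_equal(seed_inlet(geo, 1L, distribution = "centreline")$y, 0)
  # flow-weighted seeding shifts mass towards the centre
  fw <- seed_inlet(geo, 50000L, distribution = "flow_weighted", rng_seed = 4L)
  expect_lt(stats::sd(fw$y), stats::sd(s1$y))
  expect_error(seed_inlet(geo, 10L, margin = 2e-3), "margin")
  # seeding leaves the session RNG state alone
  set.seed(99); r1 <- stats::runif(1)
  set.seed(99); invisible(seed_inlet(geo, 10L)); r2 <- stats::runif(1)
  expect_identical(r1, r2)
})

test_that("Poiseuille profile oracle: centreline, no-slip, flux", {
  w <- 2e-3; vb <- 0.03
  expect_equal(poiseuille_profile(w, vb, 0), 1.5 * vb)
  expect_equal(poiseuille_profile(w, vb, c(-w / 2, w / 2)), c(0, 0))
  intg <- stats::integrate(function(y) poiseuille_profile(w, vb, y),
                           -w / 2, w / 2)
  expect_equal(intg$value, vb * w, tolerance = 1e-9)
  expect_error(poiseuille_profile(w, vb, 1.01 * w / 2), "outside")
})

test_that("settling-velocity oracle limits", {
  pp <- particle_properties()
  expect_equal(stokes_settling_velocity(pp, medium("non_conditioned")),
               3.66e-6, tolerance = 2e-3)
  neutral <- particle_properties(14e-6, 1000)
  expect_equal(stokes_settling_velocity(neutral, medium("non_conditioned")), 0)
  f2 <- fluid_properties(1000, 2 * 1.46e-3)
  expect_equal(stokes_settling_velocity(pp, f2),
               stokes_settling_velocity(pp, medium("non_conditioned")) / 2,
               tolerance = 1e-12)
})

test_that("relaxation oracle endpoints and time constant", {
  expect_equal(relaxation_oracle(1, 5, 2e-6, 0), 1)
  expect_equal(relaxation_oracle(1, 5, 2e-6, 1), 5, tolerance = 1e-9)
  expect_equal(relaxation_oracle(1, 5, 2e-6, 2e-6), 5 + (1 - 5) / exp(1))
  expect_error(relaxation_oracle(1, 5, -1, 0), "positive")
})

test_that("synthetic fields reproduce the requested velocities exactly", {
  msh <- generate_mesh(straight_channel(4e-3, 2e-3), 2e-3 / 16)
  ff <- synthetic_field(msh, function(x, y) c(0.01, -0.002))
  iv <- interp_velocity(ff, c(1e-3, 2e-3), c(0, 4e-4))
  expect_equal(iv$u, c(0.01, 0.01))
  expect_equal(iv$v, c(-0.002, -0.002))
})
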