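test_that("straight-channel solve reproduces plane Poiseuille flow", {
  ff <- ref_channel()
  expect_true(ff$converged)
  w <- 2e-3
  y <- seq(-w / 2 + 2e-5, w / 2 - 2e-5, length.out = 61)
  pr <- interp_velocity(ff, rep(5e-3, length(y)), y)
  or <- poiseuille_profile(w, ff$vbar, y)
  expect_lt(sqrt(sum((pr$u - or)^2) / sum(or^2)), 1e-3)
  # 2-D parabolic profile: max speed = 1.5 x mean speed (cell-centre
  # sampling sits h/2 off the axis, adding an O((h/w)^2) offset)
  expect_equal(max_speed(ff) / ff$vbar, 1.5, tolerance = 2e-3)
  # transverse velocity sits at the solver-tolerance noise floor
  expect_lt(max(abs(pr$v)), 5e-6 * ff$vbar)
})

test_that("divergence norm vanishes for uniform and linear solenoidal fields", {
  msh <- generate_mesh(straight_channel(4e-3, 2e-3), 2e-3 / 16)
  unif <- synthetic_field(msh, function(x, y) c(0.01, 0))
  expect_lt(divergence_norm(unif), 1e-12)
  lin <- synthetic_field(msh, function(x, y) c(x, -y))
  expect_lt(divergence_norm(lin), 1e-10)
  expect_lt(divergence_norm(ref_channel()), 1e-10)
})

test_that("boundary fluxes balance and walls carry none", {
  ff <- ref_field()
  q <- ff$q2d
  expect_equal(flux_through(ff, "inlet"), -q, tolerance = 5e-3)
  total <- flux_through(ff, "inlet") + flux_through(ff, "outlet_1") +
    flux_through(ff, "outlet_2")
  expect_lt(abs(total) / q, 5e-3)
  expect_lt(abs(flux_through(ff, "wall")), 1e-12)
  expect_error(flux_through(ff, "nonsense"), "unknown boundary tag")
})

test_that("symmetric bifurcation splits the flow 50/50 and the field mirrors", {
  ff <- ref_field()
  q1 <- flux_through(ff, "outlet_1")
  q2 <- flux_through(ff, "outlet_2")
  expect_equal(q1 / (q1 + q2), 0.5, tolerance = 5e-3)
  ny <- ff$mesh$ny
  expect_lt(max(abs(ff$u - ff$u[, ny:1])) / ff$vbar, 1e-6)
  expect_lt(max(abs(ff$v + ff$v[, (ny + 1):1])) / ff$vbar, 1e-6)
})

test_that("a low-speed pocket hugs the carina apex", {
  ff <- ref_field()
  apex <- ff$mesh$geometry$apex
  # sample within 3 particle diameters of the apex
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  r <- rep(c(1, 2, 3) * 14e-6, each = length(th))
  px <- apex[1] + r * cos(th); py <- apex[2] + r * sin(th)
  keep <- signed_wall_distance(ff$mesh$geometry, px, py) > 0
  sp <- interp_velocity(ff, px[keep], py[keep])$speed
  expect_lt(min(sp), 0.01 * ff$vbar)
})

test_that("channel Reynolds diagnostics match hand arithmetic and scaling", {
  cs <- cross_section("semicircle", diameter = 2e-3)
  bc <- boundary_conditions()        # 3 mL/min
  re <- channel_reynolds(medium("non_conditioned"), bc, cs)
  expect_equal(re, 26.6, tolerance = 2e-3)
  # doubling the viscosity halves Re exactly
  f2 <- fluid_properties(1000, 2 * 1.46e-3)
  expect_equal(channel_reynolds(f2, bc, cs), re / 2, tolerance = 1e-12)
  # Q = 0 gives Re = 0
  expect_equal(channel_reynolds(medium("fbs"), 0, cs), 0)
})

test_that("the solver refuses clearly out-of-regime configurations", {
  msh <- generate_mesh(straight_channel(), 2e-3 / 10)
  fast <- boundary_conditions(flow_rate = 1e-4)    # Re >> 500
  expect_error(solve_steady_flow(msh, medium("fbs"), fast), "Reynolds")
})

test_that("field export carries named velocity and pressure arrays", {
  ff <- ref_channel()
  f <- withr::local_tempfile(fileext = ".vtk")
  write_field_vtk(ff, f)
  lns <- readLines(f)
  expect_true(any(grepl("^VECTORS velocity double", lns)))
  expect_true(any(grepl("^SCALARS pressure double", lns)))
})
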