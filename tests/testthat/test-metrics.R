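test_that("low-velocity area: uniform flow gives zero, Poiseuille matches closed form", {
  msh <- generate_mesh(straight_channel(10e-3, 2e-3), 2e-3 / 16)
  vb <- 0.03
  unif <- synthetic_field(msh, function(x, y) c(vb, 0), vbar = vb)
  unif$vbar <- vb
  a0 <- low_velocity_area(unif, threshold_fraction = 0.5,
                          window = list(center = c(5e-3, 0), radius = 1e-3))
  expect_equal(as.numeric(a0), 0)

  w <- 2e-3
  pois <- synthetic_field(msh, function(x, y)
    c(poiseuille_profile(w, vb, max(-w / 2, min(w / 2, y))), 0), vbar = vb)
  pois$vbar <- vb
  f_max <- 0.09                      # fraction of the maximum speed
  R <- 1.2e-3
  a <- low_velocity_area(pois, threshold_fraction = 1.5 * f_max,
                         window = list(center = c(5e-3, 0), radius = R))
  # low-speed band: |y| > (w/2) sqrt(1 - f); area inside the disc window
  y0 <- (w / 2) * sqrt(1 - f_max)
  F <- function(y) y * sqrt(R^2 - y^2) + R^2 * asin(y / R)
  expected <- 2 * (F(w / 2) - F(y0))
  expect_equal(as.numeric(a), expected, tolerance = 0.03)
  # thin-band closed form: band thickness w(1 - sqrt(1-f))
  expect_equal(2 * (w / 2 - y0), w * (1 - sqrt(1 - f_max)), tolerance = 1e-12)

  # area grows with the threshold (more of the domain falls below the cut)
  a2 <- low_velocity_area(pois, threshold_fraction = 1.5 * 2 * f_max,
                          window = list(center = c(5e-3, 0), radius = R))
  expect_gt(as.numeric(a2), as.numeric(a))
  expect_error(low_velocity_area(pois, 0.01,
                                 window = list(center = c(5e-3, 1e-2),
                                               radius = 1e-4)),
               "does not intersect")
})

test_that("residence time reproduces chord-crossing oracles", {
  reg <- list(apex = c(0, 0), radius = 1e-4,
              contains = function(x, y) x^2 + y^2 <= 1e-8)
  s <- 0.01
  tt <- seq(0, 0.1, by = 1e-4)
  # central crossing: 2 r / s
  tr <- tibble::tibble(t = tt, x = -5e-4 + s * tt, y = 0)
  expect_equal(residence_time(tr, reg), 2 * 1e-4 / s, tolerance = 5e-3)
  # off-centre chord at impact parameter b: 2 sqrt(r^2 - b^2) / s
  b <- 6e-5
  trb <- tibble::tibble(t = tt, x = -5e-4 + s * tt, y = b)
  expect_equal(residence_time(trb, reg), 2 * sqrt(1e-8 - b^2) / s,
               tolerance = 5e-3)
  # a trajectory that never enters
  far <- tibble::tibble(t = tt, x = -5e-4 + s * tt, y = 5e-4)
  expect_equal(residence_time(far, reg), 0)
  expect_error(residence_time(tibble::tibble(t = numeric(0), x = numeric(0),
                                             y = numeric(0)), reg), "empty")
  expect_error(residence_time(tibble::tibble(t = c(1, 0), x = 0:1, y = 0:1),
                              reg), "time-ordered")
})

test_that("carina fraction equals a brute-force recount over stored paths", {
  ff <- ref_field()
  geo <- ff$mesh$geometry
  seeds <- seed_inlet(geo, 150L, rng_seed = 11L)
  ens <- track_particles(seeds, ff, particle_properties(),
                         medium("non_conditioned"),
                         tracking_control(max_time = 30, store_paths = 150,
                                          store_every = 1))
  apex <- geo$apex
  brute <- vapply(seq_len(150), function(id) {
    p <- ens$paths[ens$paths$particle_id == id, ]
    min(sqrt((p$x - apex[1])^2 + (p$y - apex[2])^2))
  }, numeric(1))
  r <- ens$region_radius
  # segment-based online minimum is never above the vertex-sampled one
  expect_true(all(ens$summary$min_dist_apex <= brute + 1e-12))
  expect_equal(mean(ens$summary$min_dist_apex < r), mean(brute < r),
               tolerance = 0.05)
  # fraction bounds and monotonicity in the radius
  fr <- carina_fraction(ens, radius = 14e-6 * c(2, 5, 10))
  expect_true(all(fr >= 0 & fr <= 1))
  expect_true(all(diff(fr) >= 0))
  expect_error(carina_fraction(structure(list(n = 0), class = "trajectory_ensemble")),
               "empty")
})

test_that("metrics are invariant under mirror reflection of the seeding", {
  ff <- ref_field()
  geo <- ff$mesh$geometry
  y0 <- c(2e-6, 5e-5, 3e-4)
  x0 <- rep(geo$inlet$x + 0.05 * geo$parent_length, length(y0))
  up <- track_particles(tibble::tibble(x = x0, y = y0), ff,
                        particle_properties(), medium("non_conditioned"),
                        tracking_control(max_time = 30))
  dn <- track_particles(tibble::tibble(x = x0, y = -y0), ff,
                        particle_properties(), medium("non_conditioned"),
                        tracking_control(max_time = 30))
  expect_equal(up$summary$min_dist_apex, dn$summary$min_dist_apex,
               tolerance = 1e-10)
  expect_equal(up$summary$residence_time, dn$summary$residence_time,
               tolerance = 1e-10)
})

test_that("carina region validation", {
  geo <- bifurcation_geometry(90)
  reg <- carina_region(geo, 7e-5)
  expect_true(reg$contains(5e-5, 0))
  expect_false(reg$contains(1e-4, 0))
  expect_error(carina_region(geo, -1), "positive")
  expect_error(carina_region(straight_channel(), 7e-5), "apex")
})
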