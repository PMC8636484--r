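test_that("bifurcation outlets split the opening angle symmetrically", {
  geo <- bifurcation_geometry(90, 2e-3, 10e-3, 10e-3)
  d1 <- geo$outlets$outlet_1$direction
  d2 <- geo$outlets$outlet_2$direction
  expect_equal(atan2(d1[2], d1[1]), pi / 4, tolerance = 1e-12)
  expect_equal(atan2(d2[2], d2[1]), -pi / 4, tolerance = 1e-12)
  # carina interior angle between daughter inner walls equals alpha
  for (a in c(30, 45, 90)) {
    g <- bifurcation_geometry(a)
    u1 <- g$outlets$outlet_1$direction
    u2 <- g$outlets$outlet_2$direction
    expect_equal(acos(sum(u1 * u2)) * 180 / pi, a, tolerance = 1e-10)
  }
})

test_that("geometry parameter validation rejects bad inputs", {
  expect_error(bifurcation_geometry(0), "between 0 and 180")
  expect_error(bifurcation_geometry(180), "between 0 and 180")
  expect_error(bifurcation_geometry(90, parent_length = 3e-3), "5 calibres")
  expect_error(bifurcation_geometry(90, carina_shape = "blunt",
                                    blunt_radius = 1.5e-3), "calibre / 2")
  expect_error(bifurcation_geometry(90, carina_shape = "blunt"),
               "blunt_radius")
})

test_that("blunt carina shortens the outline and converges to sharp", {
  sharp <- bifurcation_geometry(90)
  blunt <- bifurcation_geometry(90, carina_shape = "blunt",
                                blunt_radius = 0.2e-3)
  expect_lt(outline_perimeter(blunt), outline_perimeter(sharp))
  expect_gt(blunt$apex[1], sharp$apex[1])  # tip material removed
  # sharp -> blunt limit: outline Hausdorff distance shrinks with the radius
  hdist <- function(r) {
    b <- bifurcation_geometry(90, carina_shape = "blunt", blunt_radius = r)
    max(distance_to_outline(b$outline[, 1], b$outline[, 2], sharp$outline))
  }
  expect_lt(hdist(1e-5), hdist(1e-4))
  expect_lt(hdist(1e-5), 2e-5)
})

test_that("mirror symmetry: outline maps onto itself under reflection", {
  for (a in c(30, 45, 90)) {
    g <- bifurcation_geometry(a)
    refl <- cbind(g$outline[, 1], -g$outline[, 2])
    d <- distance_to_outline(refl[, 1], refl[, 2], g$outline)
    expect_lt(max(d), 1e-12)
  }
})

test_that("signed wall distance is positive inside, negative outside", {
  geo <- bifurcation_geometry(90)
  expect_gt(signed_wall_distance(geo, -5e-3, 0), 9e-4)   # parent centreline
  expect_lt(signed_wall_distance(geo, -5e-3, 1.5e-3), 0) # above the wall
  expect_equal(signed_wall_distance(geo, -5e-3, 0), 1e-3, tolerance = 1e-9)
})

test_that("geometry serialises to JSON with outline", {
  f <- withr::local_tempfile(fileext = ".json")
  write_geometry_json(bifurcation_geometry(45), f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$angle_deg, 45)
  expect_equal(j$calibre_m, 2e-3)
  expect_gt(nrow(j$outline_m), 5)
})

test_that("hydraulic diameter matches closed forms", {
  expect_equal(hydraulic_diameter(cross_section("semicircle", diameter = 2e-3)),
               4 * (pi * 1e-6 / 2) / (pi * 1e-3 + 2e-3), tolerance = 1e-12)
  expect_equal(hydraulic_diameter(cross_section("semicircle", diameter = 2e-3)),
               1.222e-3, tolerance = 1e-3)
  d <- 3.7e-3
  expect_equal(hydraulic_diameter(cross_section("circle", diameter = d)), d,
               tolerance = 1e-12)
  a <- 1.3e-3
  expect_equal(hydraulic_diameter(cross_section("rectangle", width = a,
                                                height = a)), a,
               tolerance = 1e-12)
})
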