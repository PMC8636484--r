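test_that("mesh boundary faces are each tagged exactly once and refinement quadruples cells", {
  geo <- bifurcation_geometry(90)
  m20 <- generate_mesh(geo, geo$calibre / 20)
  tags <- boundary_tag_table(m20)
  expect_setequal(tags$tag, c("wall", "inlet", "outlet_1", "outlet_2"))
  expect_true(all(tags$faces[tags$tag != "wall"] > 0))
  # every active-inactive face pair carries exactly one non-external tag
  bnd_u <- m20$uType[m20$uType != 1L & m20$uType != 0L]
  expect_true(all(bnd_u %in% 2:5))
  # 2-D refinement: halving the cell size roughly quadruples the cell count
  m40 <- generate_mesh(geo, geo$calibre / 40)
  expect_equal(m40$n_active / m20$n_active, 4, tolerance = 0.1)
  expect_lt(m40$h, m20$h)
})

test_that("mesh mask and face tags are exactly mirror-symmetric", {
  m <- generate_mesh(bifurcation_geometry(45), 2e-3 / 24)
  ny <- m$ny
  expect_identical(m$active, m$active[, ny:1])
  swap <- function(x) ifelse(x == 4L, 5L, ifelse(x == 5L, 4L, x))
  expect_identical(m$uType, swap(m$uType[, ny:1]))
  expect_identical(m$vType, swap(m$vType[, (ny + 1):1]))
  expect_equal(m$dist, m$dist[, ny:1])
})

test_that("mesh rejects too-coarse targets and degenerate outlines", {
  geo <- bifurcation_geometry(90)
  expect_error(generate_mesh(geo, geo$calibre / 5), "calibre / 10")
  expect_error(generate_mesh(geo, -1), "positive")
})

test_that("straight channel meshes with a single outlet", {
  m <- generate_mesh(straight_channel(), 2e-3 / 16)
  tags <- boundary_tag_table(m)
  expect_equal(unname(tags$faces[tags$tag == "outlet_2"]), 0L)
  expect_equal(unname(tags$faces[tags$tag == "inlet"]), 16L)
  expect_equal(m$n_active, m$nx * m$ny)  # rectangle: every cell active
})

test_that("signed distance field tracks the staircase wall near boundaries", {
  geo <- straight_channel()
  m <- generate_mesh(geo, 2e-3 / 20)
  h <- m$h
  # wall-adjacent cell centre sits half a cell from the wall face
  expect_equal(m$dist[5, 1], h / 2, tolerance = 1e-12)
  expect_equal(m$dist[5, m$ny], h / 2, tolerance = 1e-12)
  # interior centre distance matches exact geometry
  j_mid <- m$ny / 2
  expect_equal(m$dist[5, j_mid], abs(m$y0 + (j_mid - 0.5) * h - (-1e-3)),
               tolerance = 1e-9)
})

test_that("mesh export writers produce parsable VTK and MSH files", {
  m <- generate_mesh(straight_channel(4e-3, 1e-3), 1e-3 / 10)
  fv <- withr::local_tempfile(fileext = ".vtk")
  write_mesh_vtk(m, fv)
  lns <- readLines(fv)
  expect_equal(lns[1], "# vtk DataFile Version 3.0")
  np <- as.integer(strsplit(grep("^POINTS", lns, value = TRUE), " ")[[1]][2])
  expect_equal(np, (m$nx + 1) * (m$ny + 1))
  fm <- withr::local_tempfile(fileext = ".msh")
  write_mesh_msh(m, fm)
  lns <- readLines(fm)
  expect_equal(lns[2], "2.2 0 8")
  expect_true(any(lns == "$EndElements"))
})
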