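test_that("structured tube meshes are closed, manifold and oriented", {
  cyl <- fx_cylinder()
  expect_true(is_watertight(cyl))
  expect_equal(euler_characteristic(cyl), 2)
  expect_equal(count_boundary_edges(cyl), 0)
  # lateral area + caps of a cylinder r=10, L=60 (n_circ=96 polygon slightly
  # inscribed, so just under the smooth value)
  expect_equal(surface_area(cyl), 2 * pi * 10 * 60 + 2 * pi * 100,
               tolerance = 2e-3)
})

test_that("surface area and topology are invariant under rigid transforms", {
  cyl <- fx_cylinder()
  set.seed(11)
  rot <- random_rotation()
  moved <- transform_surface(cyl, rot, c(5, -3, 12))
  expect_equal(surface_area(moved), surface_area(cyl), tolerance = 1e-12)
  expect_true(is_watertight(moved))
})

test_that("ASCII STL round-trips a surface", {
  cyl <- make_cylinder_tube(20, 5, n_circ = 24, n_axial = 6)
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(cyl, path)
  back <- read_stl(path)
  expect_equal(nrow(back$faces), nrow(cyl$faces))
  expect_true(is_watertight(back))
  expect_equal(surface_area(back), surface_area(cyl), tolerance = 1e-6)
})

test_that("marching tetrahedra reproduces a sphere accurately", {
  f <- function(p) sqrt(rowSums(p^2)) - 10
  g <- seq(-13, 13, by = 1)
  s <- marching_tets(f, g, g, g)
  expect_true(is_watertight(s))
  expect_equal(euler_characteristic(s), 2)
  expect_equal(surface_area(s), 4 * pi * 100, tolerance = 0.01)
  # outward orientation: positive enclosed volume
  fc <- pauhemo:::face_corners(s)
  vol <- sum(rowSums(fc$a * pauhemo:::cross3(fc$b, fc$c))) / 6
  expect_equal(vol, 4 / 3 * pi * 1000, tolerance = 0.01)
})

test_that("degenerate face/vertex inputs are rejected", {
  expect_error(tri_surface(matrix(0, 3, 2), matrix(1L, 1, 3)), "3 columns")
  expect_error(tri_surface(matrix(0, 3, 3), matrix(4L, 1, 3)), "out of range")
})
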