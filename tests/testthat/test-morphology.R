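test_that("cylinder cross-sections recover area and diameter analytically", {
  sec <- extract_sections(fx_cylinder(), fx_axis_cl(), 5, 55, spacing = 10)
  expect_equal(mean(sec$area_cm2), pi, tolerance = 0.01)       # r = 10 mm
  expect_equal(mean(sec$dmax_cm), 2.00, tolerance = 0.01)
  # Dmax bounds the equivalent-circle diameter
  expect_true(all(sec$dmax_cm >= 2 * sqrt(sec$area_cm2 / pi) - 1e-6))
})

test_that("tapered cone sections have a linear diameter profile", {
  cone <- make_cylinder_tube(60, c(10, 5))
  sec <- extract_sections(cone, fx_axis_cl(), 5, 55, spacing = 5)
  expected <- 2 - sec$station_mm / 60  # D(s) = 20 - 10 s/60 mm -> cm
  expect_equal(sec$dmax_cm, expected, tolerance = 0.02)
})

test_that("elliptical sections report the major axis as Dmax", {
  ell <- make_cylinder_tube(60, 10, ellipse_ratio = 0.6)
  sec <- extract_sections(ell, fx_axis_cl(), 25, 35, spacing = 5)
  expect_equal(mean(sec$dmax_cm), 2.0, tolerance = 0.01)
  expect_equal(mean(sec$area_cm2), pi * 1.0 * 0.6, tolerance = 0.01)
})

test_that("section stations outside the centerline are rejected", {
  expect_error(extract_sections(fx_cylinder(), fx_axis_cl(), 10, 80),
               "outside centerline")
})

test_that("centerline of a straight cylinder stays on the axis", {
  cl <- compute_centerline(fx_cylinder(), c(0.5, 0.4, 2), c(0, 0, 58), step = 2,
                           initial_direction = c(0, 0, 1))
  off_axis <- sqrt(cl$x^2 + cl$y^2)
  expect_lt(max(off_axis), 0.05 * 10)
})

test_that("centerline of a torus-segment tube tracks the parametric circle", {
  tor <- make_arc_tube(30, 180, 5)
  cl <- compute_centerline(tor, c(30, 0, 1), c(-30, 0, 1), step = 1.5,
                           initial_direction = c(0, 0, 1))
  radial_dev <- abs(sqrt(cl$x^2 + cl$z^2) - 30)
  expect_lt(max(radial_dev), 0.02 * 5)
  expect_lt(max(abs(cl$y)), 0.02 * 5)
})

test_that("centerline extraction is equivariant under rigid motion", {
  set.seed(5)
  rot <- random_rotation()
  shift <- c(-4, 7, 3)
  cyl <- fx_cylinder()
  moved <- transform_surface(cyl, rot, shift)
  cl0 <- compute_centerline(cyl, c(0, 0, 2), c(0, 0, 58), step = 2,
                            initial_direction = c(0, 0, 1))
  cl1 <- compute_centerline(moved, as.vector(rot %*% c(0, 0, 2)) + shift,
                            as.vector(rot %*% c(0, 0, 58)) + shift, step = 2,
                            initial_direction = as.vector(rot %*% c(0, 0, 1)))
  # map the moved-frame centerline back and check it lies on the cylinder
  # axis to the same tolerance as the unmoved extraction
  p1 <- sweep(pauhemo:::cl_points(cl1), 2, shift) %*% rot
  expect_lt(max(sqrt(p1[, 1]^2 + p1[, 2]^2)), 0.05 * 10)
  expect_equal(cl_length(cl1), cl_length(cl0), tolerance = 0.05)
})

test_that("marching aborts with a diagnostic when it cannot reach the target", {
  expect_error(
    compute_centerline(fx_cylinder(), c(0, 0, 2), c(200, 0, 30), step = 2,
                       initial_direction = c(0, 0, 1), max_iter = 10),
    "failed to reach|exited the surface")
})

test_that("bifurcation angle matches analytic polyline constructions", {
  ao <- centerline(cbind(seq(0, 100), 0, 0), "AO")
  perp <- centerline(cbind(50, 0, seq(0, 30)), "branch")
  expect_equal(bifurcation_angle(ao, perp, d_branch = 12), 90, tolerance = 1)
  tangent <- centerline(cbind(seq(50, 80), 0, 0), "branch")
  expect_equal(bifurcation_angle(ao, tangent, d_branch = 12), 0, tolerance = 1)
  o45 <- centerline(cbind(50 + seq(0, 30) / sqrt(2), 0, seq(0, 30) / sqrt(2)), "b45")
  expect_equal(bifurcation_angle(ao, o45, d_branch = 12), 45, tolerance = 1)
  expect_error(bifurcation_angle(ao, perp, d_branch = 40), "shorter than")
})

test_that("mesh-measured angles recover generator-specified values", {
  v <- fx_straight("PRE")
  truth <- straight_branches()
  cl_ao <- NULL
  for (i in seq_len(nrow(truth))) {
    ang <- measure_branch_angle(v, truth$label[i])
    expect_equal(ang, truth$angle_deg[i], tolerance = 2,
                 label = sprintf("angle(%s)", truth$label[i]))
  }
})

test_that("tortuosity matches closed forms", {
  straight <- centerline(cbind(seq(0, 50), 0, 0))
  expect_equal(tortuosity(straight), 0, tolerance = 1e-9)
  th <- seq(0, pi, length.out = 401)
  semi <- centerline(cbind(30 * cos(th), 0, 30 * sin(th)), "semi")
  expect_equal(tortuosity(semi), pi / 2 - 1, tolerance = 0.01)
  thq <- seq(0, pi / 2, length.out = 201)
  quarter <- centerline(cbind(30 * cos(thq), 0, 30 * sin(thq)), "quarter")
  expect_equal(tortuosity(quarter), (pi / 4) / (sqrt(2) / 2) - 1, tolerance = 0.01)
  expect_equal(tortuosity(semi, index = "ratio"), pi / 2, tolerance = 0.01)
  loop <- centerline(cbind(c(0, 1, 0), c(0, 1, 1e-12), c(0, 1, 0)))
  expect_error(tortuosity(loop), "coincide")
})

test_that("branch summaries aggregate sections and pass metadata through", {
  sec <- extract_sections(fx_cylinder(), fx_axis_cl(), 10, 50, spacing = 10)
  s <- summarize_branch(sec, theta = 87.3, tort = 0.29)
  expect_equal(s$avg_dmax_cm, sec$dmax_cm[1], tolerance = 1e-3)
  expect_equal(s$avg_area_cm2, sec$area_cm2[1], tolerance = 1e-3)
  expect_equal(s$theta_deg, 87.3)
  expect_equal(s$tortuosity, 0.29)
  expect_equal(s$n_sections, nrow(sec))
  expect_error(summarize_branch(sec[0, ]), "at least one", ignore.case = TRUE)
})

test_that("percent reduction reproduces the printed case-averaged values", {
  # averaged maximum diameters before/after stent placement, third case
  expect_equal(percent_reduction(1.37, 1.20), 12.4, tolerance = 0.1)
  expect_equal(percent_reduction(10, 5), 50)
  expect_error(percent_reduction(0, 1), "positive")
})
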