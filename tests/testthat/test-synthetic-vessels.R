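test_that("aorta specs enforce their invariants", {
  expect_error(aorta_spec("PRE", lsa_narrowing = 0.2), "SBSG")
  expect_error(aorta_spec("SBSG", branches = default_branches()[1:2, ]), "LSA")
  br <- default_branches()
  br$position_deg <- c(85, 55, 112)
  expect_error(aorta_spec("PRE", branches = br), "strictly increasing")
  br <- default_branches()
  br$diameter_mm[1] <- 30
  expect_error(aorta_spec("PRE", branches = br), "smaller than the inlet")
})

test_that("colliding branches are rejected with a diagnostic naming them", {
  br <- default_branches()
  br$position_deg <- c(55, 58, 112)  # BCA and LCCA ~1.6 mm apart on the arch
  expect_error(make_aorta(aorta_spec("PRE", branches = br)),
               "BCA and LCCA collide")
})

test_that("generated surfaces are watertight across configurations", {
  for (v in list(fx_vessel("PRE"), fx_vessel("SBSG", 0.124), fx_vessel("HYBRID"))) {
    expect_true(is_watertight(v$surface))
    expect_equal(euler_characteristic(v$surface), 2)
    expect_equal(count_boundary_edges(v$surface), 0)
  }
})

test_that("watertightness holds over a seeded sample of spec variations", {
  set.seed(42)
  for (i in 1:3) {
    br <- default_branches()
    br$diameter_mm <- br$diameter_mm * stats::runif(3, 0.85, 1.1)
    br$angle_deg <- br$angle_deg + stats::runif(3, -15, 10)
    spec <- aorta_spec(sample(c("PRE", "SBSG"), 1),
                       arch_radius = stats::runif(1, 28, 34),
                       inlet_diameter = stats::runif(1, 24, 28),
                       branches = br,
                       lsa_narrowing = 0,
                       pau_bulge = if (i == 2) list(position_deg = 140, depth_mm = 6),
                       mesh_resolution = 2, seed = i)
    v <- make_aorta(spec)
    expect_true(is_watertight(v$surface))
  }
})

test_that("ground-truth angles equal the specified branch angles", {
  v <- fx_vessel("PRE")
  expect_equal(unname(v$truth_angles[c("BCA", "LCCA", "LSA")]),
               default_branches()$angle_deg)
  vs <- fx_straight("PRE")
  expect_equal(unname(vs$truth_angles), straight_branches()$angle_deg)
})

test_that("SBSG narrows the proximal LSA by the requested diameter fraction", {
  pre <- fx_straight("PRE")
  sbsg <- fx_straight("SBSG", 0.124)
  m_pre <- measure_lsa_morphometry(pre)
  m_sbsg <- measure_lsa_morphometry(sbsg)
  ratio <- m_sbsg$sections$dmax_cm[1] / m_pre$sections$dmax_cm[1]
  expect_equal(ratio, 1 - 0.124, tolerance = 0.02)
})

test_that("HYBRID removes the LSA origin and routes an 8 mm bypass", {
  v <- fx_vessel("HYBRID")
  sk <- v$skeleton
  # no branch segment leaves the arch at the LSA take-off
  from_jlsa <- sk[sk$from == "j_LSA", ]
  expect_true(all(from_jlsa$to == "t_DA"))
  bypass <- sk[sk$label == "bypass", ]
  expect_equal(nrow(bypass), 1)
  expect_equal(bypass$diameter_mm, 8)
  expect_true(bypass$from == "n_LCCA_mid")
})

test_that("ground truth is invariant under rigid motion of the mesh", {
  v <- fx_straight("PRE")
  set.seed(3)
  rot <- random_rotation()
  shift <- c(10, -20, 5)
  moved <- transform_surface(v$surface, rot, shift)
  # re-measure a branch centerline on the moved mesh; compare in moved frame
  tr <- v$truth_centerlines$BCA
  seed_pt <- as.vector(rot %*% cl_point_at(tr, 17)) + shift
  tgt <- as.vector(rot %*% cl_point_at(tr, 36)) + shift
  dir0 <- as.vector(rot %*% cl_tangent_at(tr, 5))
  cl_moved <- compute_centerline(moved, seed_pt, tgt, step = 1.5,
                                 initial_direction = dir0, r_hint = 6)
  cl_orig <- compute_centerline(v$surface, cl_point_at(tr, 17),
                                cl_point_at(tr, 36), step = 1.5,
                                initial_direction = cl_tangent_at(tr, 5),
                                r_hint = 6)
  expect_equal(tortuosity(cl_moved), tortuosity(cl_orig), tolerance = 1e-6)
  expect_equal(cl_length(cl_moved), cl_length(cl_orig), tolerance = 1e-6)
})

test_that("waveform integral equals the stroke volume by construction", {
  q <- make_waveform(period = 0.85, stroke_volume_mL = 70)
  expect_equal(waveform_integral(q), 70, tolerance = 1e-9)
  # refinement leaves the integral unchanged
  q2 <- make_waveform(period = 0.85, stroke_volume_mL = 70, n_samples = 512)
  expect_equal(waveform_integral(q2), 70, tolerance = 1e-9)
  expect_equal(waveform_integral(q2) / waveform_integral(q), 1, tolerance = 1e-3)
})

test_that("waveform shape parameters behave as documented", {
  q0 <- make_waveform(dip_frac = 0)
  expect_gte(min(q0$q_mL_s), 0)
  qd <- make_waveform(dip_frac = 0.08)
  expect_lt(min(qd$q_mL_s), 0)
  expect_error(make_waveform(period = -1), "positive")
  expect_error(make_waveform(stroke_volume_mL = 0), "positive")
})

test_that("synthetic WSS fields carry exact analytic ground truth", {
  s <- fx_patch()
  f0 <- make_wss_field(s, base_magnitude = 2, oscillation = 0, n_steps = 16,
                       noise = 0)
  expect_equal(compute_tawss(f0), rep(2, nrow(s$vertices)), tolerance = 1e-12)
  expect_equal(max(abs(compute_osi(f0))), 0, tolerance = 1e-12)
  f1 <- make_wss_field(s, base_magnitude = 2, oscillation = 1, n_steps = 16,
                       noise = 0)
  expect_equal(compute_osi(f1), rep(0.5, nrow(s$vertices)), tolerance = 1e-12)
  # spatially varying magnitude and reversal fraction, with magnitude jitter
  f <- make_wss_field(s, base_magnitude = function(v) 1 + 0.1 * abs(v[, 3]),
                      oscillation = function(v) pmin(1, abs(v[, 1]) / 5),
                      n_steps = 32, noise = 0.05, seed = 7)
  expect_equal(compute_tawss(f), attr(f, "truth_tawss"), tolerance = 1e-9)
  expect_equal(compute_osi(f), attr(f, "truth_osi"), tolerance = 1e-9)
  expect_error(make_wss_field(s, n_steps = 15), "even")
  expect_error(make_wss_field(s, n_steps = 4), "at least 8")
})

test_that("waveform and WSS series round-trip through their text formats", {
  q <- make_waveform(n_samples = 64)
  p <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(q, p)
  q2 <- read_waveform_csv(p)
  expect_equal(q2$q_mL_s, q$q_mL_s, tolerance = 1e-6)
  expect_equal(attr(q2, "period"), 0.85, tolerance = 1e-9)

  s <- fx_patch()
  f <- make_wss_field(s, n_steps = 8, noise = 0)
  pw <- withr::local_tempfile(fileext = ".txt")
  write_wss_series(f, pw)
  f2 <- read_wss_series(pw, s)
  expect_equal(f2$values, f$values, tolerance = 1e-6)
  expect_equal(f2$period, f$period)
})
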