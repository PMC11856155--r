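single_node_series <- function(vectors, period = 0.85) {
  # a wss_series on a minimal tetrahedron surface, values on node 1 only
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  faces <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  s <- tri_surface(verts, faces)
  n_steps <- nrow(vectors)
  vals <- array(0, dim = c(4, n_steps, 3))
  for (i in 1:4) vals[i, , ] <- vectors
  wss_series(s, vals, period)
}

test_that("TAWSS integrates the magnitude over the cycle", {
  const <- single_node_series(matrix(rep(c(2, 0, 0), 32), ncol = 3, byrow = TRUE))
  expect_equal(compute_tawss(const), rep(2, 4), tolerance = 1e-12)
  # rectified sine magnitude: mean of |A sin| = 2A/pi
  tt <- tgrid(0.85, 64)
  vec <- cbind(3 * sin(2 * pi * tt / 0.85), 0, 0)
  s <- single_node_series(vec)
  expect_equal(compute_tawss(s), rep(2 * 3 / pi, 4), tolerance = 5e-3)
})

test_that("OSI spans its range: 0 for fixed direction, 0.5 for reversal", {
  tt <- tgrid(0.85, 32)
  fixed <- single_node_series(cbind(1 + abs(sin(2 * pi * tt / 0.85)), 0, 0))
  expect_equal(compute_osi(fixed), rep(0, 4), tolerance = 1e-12)
  w <- 1.7
  rev <- single_node_series(cbind(c(rep(w, 16), rep(-w, 16)), 0, 0))
  expect_equal(compute_osi(rev), rep(0.5, 4), tolerance = 1e-12)
})

test_that("a rotating WSS vector matches the brute-force vector-sum oracle", {
  for (phi_deg in c(30, 90, 170, 360)) {
    tt <- tgrid(0.85, 48)
    ang <- phi_deg * pi / 180 * tt / 0.85
    vec <- cbind(cos(ang), sin(ang), 0) * 1.4
    s <- single_node_series(vec)
    expect_equal(compute_osi(s), osi_brute(s), tolerance = 1e-6)
    expect_equal(compute_tawss(s), tawss_brute(s), tolerance = 1e-9)
  }
})

test_that("ECAP divides OSI by TAWSS with floor masking", {
  expect_equal(compute_ecap(0.5, 0.25), 0.5)
  expect_true(is.na(compute_ecap(1e-9, 0.2)))
  set.seed(13)
  tawss <- stats::runif(50, 0.1, 3)
  osi <- stats::runif(50, 0, 0.5)
  expect_equal(compute_ecap(tawss, osi), osi / tawss, tolerance = 1e-12)
})

test_that("OSI stays within [0, 0.5] for seeded random fields", {
  set.seed(31)
  for (rep in 1:5) {
    vec <- matrix(stats::rnorm(48 * 3), ncol = 3)
    s <- single_node_series(vec)
    osi <- compute_osi(s)
    expect_true(all(osi >= -1e-12 & osi <= 0.5 + 1e-12))
  }
})

test_that("indicators transform correctly under rotation and rescaling", {
  s <- fx_patch()
  f <- make_wss_field(s, base_magnitude = function(v) 0.5 + 0.05 * abs(v[, 3]),
                      oscillation = 0.8, n_steps = 32, noise = 0.05, seed = 2)
  t0 <- compute_tawss(f); o0 <- compute_osi(f)
  set.seed(8)
  rot <- random_rotation()
  f_rot <- f
  f_rot$surface <- transform_surface(s, rot)
  for (k in seq_len(f$n_steps)) f_rot$values[, k, ] <- f$values[, k, ] %*% t(rot)
  expect_equal(compute_tawss(f_rot), t0, tolerance = 1e-12)
  expect_equal(compute_osi(f_rot), o0, tolerance = 1e-12)
  f_scaled <- f
  f_scaled$values <- f$values * 3.7
  expect_equal(compute_tawss(f_scaled), 3.7 * t0, tolerance = 1e-12)
  expect_equal(compute_osi(f_scaled), o0, tolerance = 1e-12)
})

test_that("halving the time step barely changes smooth-field indicators", {
  s <- fx_patch()
  mk <- function(n) make_wss_field(s, base_magnitude = 1.2, oscillation = 0.9,
                                   n_steps = n, noise = 0)
  t1 <- compute_tawss(mk(32)); t2 <- compute_tawss(mk(64))
  o1 <- compute_osi(mk(32)); o2 <- compute_osi(mk(64))
  expect_lt(max(abs(t2 - t1) / t1), 2e-3)
  expect_lt(max(abs(o2 - o1)), 2e-3)
})

test_that("exposed area classifies triangle means against thresholds", {
  s <- fx_patch()
  n <- nrow(s$vertices)
  expect_equal(exposed_area(rep(0.1, n), s, 0.4, "below"), 100)
  expect_equal(exposed_area(rep(0.1, n), s, 0.4, "above"), 0)
  # split a cylinder by axial position: z < 15 covers half the lateral area
  vals <- ifelse(s$vertices[, 3] < 15, 0.1, 1)
  got <- exposed_area(vals, s, 0.4, "below")
  expect_equal(got, 50, tolerance = 5)
  set.seed(17)
  rnd <- stats::runif(n, 0, 1)
  expect_equal(exposed_area(rnd, s, 0.5, "below"),
               exposed_area_brute(rnd, s, 0.5, "below"), tolerance = 1e-12)
  expect_equal(exposed_area(rnd, s, 0.5, "below") +
                 exposed_area(rnd, s, 0.5, "above"), 100, tolerance = 1e-9)
})

test_that("masked nodes are excluded from exposure statistics", {
  s <- fx_patch()
  n <- nrow(s$vertices)
  vals <- rep(1, n)
  vals[s$vertices[, 3] > 25] <- NA
  pct <- exposed_area(vals, s, 0.4, "above")
  expect_equal(pct, 100)
  rep <- exposure_report(indicator_maps(make_wss_field(s, n_steps = 16, noise = 0)))
  expect_true(all(!is.na(rep$area_low_tawss_pct)))
  expect_gt(rep$total_area_m2, 0)
})
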