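# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# uniform time grid over [0, T)
tgrid <- function(T, n) seq(0, T, length.out = n + 1)[seq_len(n)]

# straight-aorta branch layout for analytic angle checks (chord == tangent)
straight_branches <- function() {
  tibble::tibble(label = c("BCA", "LCCA", "LSA"),
                 position_deg = c(30, 55, 80),
                 diameter_mm = c(12, 9, 11),
                 angle_deg = c(90, 60, 45),
                 length_mm = c(40, 40, 45))
}

fx_vessel <- function(config = "PRE", narrowing = 0) {
  fixture(paste0("vessel_", config, "_", narrowing), function() {
    make_aorta(aorta_spec(config, lsa_narrowing = narrowing,
                          mesh_resolution = 1.8))
  })
}

fx_straight <- function(config = "PRE", narrowing = 0) {
  fixture(paste0("straight_", config, "_", narrowing), function() {
    make_aorta(aorta_spec(config, arch_sweep_deg = 0,
                          branches = straight_branches(),
                          lsa_narrowing = narrowing,
                          mesh_resolution = 1.8))
  })
}

fx_cylinder <- function() {
  fixture("cylinder", function() make_cylinder_tube(60, 10))
}

fx_axis_cl <- function() {
  fixture("axis_cl", function() centerline(cbind(0, 0, seq(0, 60, by = 1)), "axis"))
}

fx_waveform <- function() fixture("waveform", function() make_waveform())

# small closed surface for WSS fields
fx_patch <- function() {
  fixture("patch", function() make_cylinder_tube(30, 5, n_circ = 24, n_axial = 8))
}

random_rotation <- function() {
  # QR of a random matrix, det forced to +1
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# brute-force OSI/TAWSS oracles: explicit per-node loops over the definition
tawss_brute <- function(series) {
  n <- dim(series$values)[1]
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_len(series$n_steps)) {
      acc <- acc + sqrt(sum(series$values[i, k, ]^2)) * series$dt
    }
    out[i] <- acc / series$period
  }
  out
}

osi_brute <- function(series) {
  n <- dim(series$values)[1]
  out <- numeric(n)
  for (i in seq_len(n)) {
    vec <- c(0, 0, 0); mag <- 0
    for (k in seq_len(series$n_steps)) {
      vec <- vec + series$values[i, k, ] * series$dt
      mag <- mag + sqrt(sum(series$values[i, k, ]^2)) * series$dt
    }
    out[i] <- if (mag > 0) 0.5 * (1 - sqrt(sum(vec^2)) / mag) else NA_real_
  }
  out
}

exposed_area_brute <- function(values, surface, threshold, direction) {
  f <- surface$faces
  num <- 0; tot <- 0
  for (t in seq_len(nrow(f))) {
    a <- surface$vertices[f[t, 1], ]
    b <- surface$vertices[f[t, 2], ]
    cc <- surface$vertices[f[t, 3], ]
    ar <- 0.5 * sqrt(sum(pracma::cross(b - a, cc - a)^2))
    mv <- mean(values[f[t, ]])
    if (is.na(mv)) next
    tot <- tot + ar
    pass <- if (direction == "below") mv < threshold else mv > threshold
    if (pass) num <- num + ar
  }
  100 * num / tot
}
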