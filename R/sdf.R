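# Signed-distance-style implicit primitives (negative inside), vectorised over
# an n x 3 point matrix. Exactness of the distance is not required by the
# polygoniser -- only the correct sign and near-linearity close to the surface,
# which all of these satisfy.

unit3 <- function(v) v / sqrt(sum(v^2))

sdf_sphere <- function(p, center, r) {
  sqrt(rowSums(sweep(p, 2, center)^2)) - r
}

# finite capsule: segment a-b with radius r (spherical ends)
sdf_capsule <- function(p, a, b, r) {
  ab <- b - a
  L2 <- sum(ab^2)
  pa <- sweep(p, 2, a)
  t <- pmin(pmax((pa %*% ab) / L2, 0), 1)
  d <- pa - outer(as.vector(t), ab)
  sqrt(rowSums(d^2)) - r
}

# tapered capsule along segment a-b, radius ra at a linearly to rb at b
sdf_round_cone <- function(p, a, b, ra, rb) {
  ab <- b - a
  L2 <- sum(ab^2)
  pa <- sweep(p, 2, a)
  t <- pmin(pmax((pa %*% ab) / L2, 0), 1)
  d <- pa - outer(as.vector(t), ab)
  sqrt(rowSums(d^2)) - (ra + as.vector(t) * (rb - ra))
}

# circular-arc tube: arc of radius R in the plane spanned by (u, w) through
# `center`, angles phi in [phi0, phi1] (radians, measured from u towards w),
# tube radius r; spherical ends. Exact distance to the clamped arc.
sdf_arc_tube <- function(p, center, u, w, R, phi0, phi1, r) {
  u <- unit3(u); w <- unit3(w)
  pc <- sweep(p, 2, center)
  pu <- pc %*% u
  pw <- pc %*% w
  nrm <- unit3(pracma_cross(u, w))
  pn <- pc %*% nrm
  phi <- atan2(pw, pu)
  # map into [phi0, phi1] handling wrap: arcs used here span < 2*pi
  phi <- ifelse(phi < phi0 - pi, phi + 2 * pi, phi)
  phic <- pmin(pmax(phi, phi0), phi1)
  qx <- R * cos(phic); qy <- R * sin(phic)
  sqrt((pu - qx)^2 + (pw - qy)^2 + pn^2) - r
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# tube of constant radius around a sampled curve (n_pts x 3), as the union of
# consecutive capsules; accurate to O(ds^2/rho) for smooth curves
sdf_polyline_tube <- function(p, pts, r) {
  d <- rep(Inf, nrow(p))
  for (i in seq_len(nrow(pts) - 1)) {
    d <- pmin(d, sdf_capsule(p, pts[i, ], pts[i + 1, ], r))
  }
  d
}

sdf_union <- function(...) {
  fs <- list(...)
  function(p) {
    d <- fs[[1]](p)
    for (f in fs[-1]) d <- pmin(d, f(p))
    d
  }
}
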