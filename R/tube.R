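# Structured tube meshes with exact parametric geometry, used as analytic test
# shapes (sections of known area/diameter, torus tubes with known centerline).

#' Structured tube meshes around a parametric centerline
#'
#' `sweep_tube()` lofts elliptical rings along a polyline centerline with
#' supplied in-plane frame vectors and closes both ends with triangle fans,
#' producing a watertight, consistently oriented surface whose cross-sections
#' are exact ellipses. `make_cylinder_tube()` and `make_arc_tube()` are
#' convenience wrappers for straight (optionally tapered / elliptical) tubes
#' and circular-arc tubes.
#'
#' @param centers `n x 3` matrix of ring centers (mm).
#' @param normal1,normal2 `n x 3` matrices of (unit) in-plane frame vectors.
#' @param a,b Semi-axes per ring (mm), recycled.
#' @param n_circ Vertices per ring.
#' @return A [tri_surface()].
#' @export
sweep_tube <- function(centers, normal1, normal2, a, b = a, n_circ = 96) {
  n_ring <- nrow(centers)
  a <- rep_len(a, n_ring); b <- rep_len(b, n_ring)
  th <- seq(0, 2 * pi, length.out = n_circ + 1)[seq_len(n_circ)]
  verts <- matrix(0, n_ring * n_circ + 2, 3)
  for (i in seq_len(n_ring)) {
    ring <- centers[rep(i, n_circ), ] +
      outer(a[i] * cos(th), normal1[i, ]) + outer(b[i] * sin(th), normal2[i, ])
    verts[(i - 1) * n_circ + seq_len(n_circ), ] <- ring
  }
  c0 <- n_ring * n_circ + 1L  # start cap center
  c1 <- n_ring * n_circ + 2L  # end cap center
  verts[c0, ] <- centers[1, ]
  verts[c1, ] <- centers[n_ring, ]

  faces <- list()
  idx <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  for (i in seq_len(n_ring - 1)) {
    j <- seq_len(n_circ)
    faces[[length(faces) + 1]] <- cbind(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
    faces[[length(faces) + 1]] <- cbind(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
  }
  j <- seq_len(n_circ)
  faces[[length(faces) + 1]] <- cbind(rep(c0, n_circ), idx(1, j), idx(1, j + 1))
  faces[[length(faces) + 1]] <- cbind(rep(c1, n_circ), idx(n_ring, j + 1), idx(n_ring, j))
  s <- tri_surface(verts, do.call(rbind, faces))
  orient_outward(s)
}

# flip all faces if the signed volume is negative (divergence theorem)
orient_outward <- function(surface) {
  fc <- face_corners(surface)
  vol <- sum(rowSums(fc$a * cross3(fc$b, fc$c))) / 6
  if (vol < 0) surface$faces <- surface$faces[, c(1, 3, 2)]
  surface
}

#' @rdname sweep_tube
#' @param length Tube length (mm) along `axis`.
#' @param radius Radius (mm): scalar, length-2 (linear taper start/end), or a
#'   function of arc length.
#' @param axis Tube axis direction.
#' @param origin Start point (mm).
#' @param ellipse_ratio Ratio b/a of the section semi-axes.
#' @param n_axial Number of rings.
#' @export
make_cylinder_tube <- function(length, radius, axis = c(0, 0, 1),
                               origin = c(0, 0, 0), ellipse_ratio = 1,
                               n_circ = 96, n_axial = 40) {
  axis <- unit3(axis)
  s <- seq(0, length, length.out = n_axial)
  r <- if (is.function(radius)) radius(s)
       else if (base::length(radius) == 2) radius[1] + (radius[2] - radius[1]) * s / length
       else rep(radius, n_axial)
  centers <- outer(s, axis) + matrix(origin, n_axial, 3, byrow = TRUE)
  ref <- diag(3)[which.min(abs(axis)), ]
  n1 <- unit3(ref - axis * sum(ref * axis))
  n2 <- pracma_cross(axis, n1)
  sweep_tube(centers, matrix(n1, n_axial, 3, byrow = TRUE),
             matrix(n2, n_axial, 3, byrow = TRUE),
             a = r, b = r * ellipse_ratio, n_circ = n_circ)
}

#' @rdname sweep_tube
#' @param arc_radius Radius of the centerline arc (mm).
#' @param sweep_deg Arc sweep angle in degrees.
#' @param tube_radius Tube radius (mm).
#' @param center Arc center (mm).
#' @export
make_arc_tube <- function(arc_radius, sweep_deg, tube_radius, center = c(0, 0, 0),
                          n_circ = 96, n_axial = 80) {
  phi <- seq(0, sweep_deg * pi / 180, length.out = n_axial)
  centers <- cbind(arc_radius * cos(phi), 0, arc_radius * sin(phi))
  centers <- sweep(centers, 2, center, "+")
  n1 <- cbind(cos(phi), 0, sin(phi))          # radial, in arc plane
  n2 <- matrix(c(0, 1, 0), n_axial, 3, byrow = TRUE)
  sweep_tube(centers, n1, n2, a = tube_radius, n_circ = n_circ)
}
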