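#' Triangulated vessel surfaces
#'
#' A `tri_surface` holds a triangulated lumen wall: an `n x 3` matrix of vertex
#' coordinates in millimetres and an `m x 3` integer matrix of 1-based face
#' indices with consistent (outward) winding. It is the geometric substrate for
#' centerline extraction, cross-sectioning and wall-shear-stress maps.
#'
#' @param vertices Numeric matrix, `n x 3`, vertex coordinates in mm.
#' @param faces Integer matrix, `m x 3`, 1-based vertex indices per triangle.
#' @return A `tri_surface` object.
#' @export
tri_surface <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) abort("`vertices` must have 3 columns.")
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices))) {
    abort("`faces` indices out of range.")
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("<tri_surface: %d vertices, %d faces, area %.1f mm^2%s>\n",
              nrow(x$vertices), nrow(x$faces), surface_area(x),
              if (is_watertight(x)) ", watertight" else ""))
  invisible(x)
}

#' @rdname tri_surface
#' @param x A `tri_surface`.
#' @export
is_tri_surface <- function(x) inherits(x, "tri_surface")

face_corners <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  list(a = v[f[, 1], , drop = FALSE],
       b = v[f[, 2], , drop = FALSE],
       c = v[f[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Per-triangle and total surface area
#'
#' @param surface A [tri_surface()].
#' @return `triangle_areas()` returns a vector of triangle areas (mm^2);
#'   `surface_area()` their sum.
#' @export
triangle_areas <- function(surface) {
  fc <- face_corners(surface)
  cr <- cross3(fc$b - fc$a, fc$c - fc$a)
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname triangle_areas
#' @export
surface_area <- function(surface) sum(triangle_areas(surface))

# Directed edge table: each row (i, j) for the half-edge i->j of every face.
half_edges <- function(faces) {
  rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
}

#' Watertightness and manifoldness checks
#'
#' A closed, consistently oriented triangulation has every undirected edge
#' shared by exactly two faces, each direction appearing exactly once.
#'
#' @param surface A [tri_surface()].
#' @return Logical scalar.
#' @export
is_watertight <- function(surface) {
  he <- half_edges(surface$faces)
  key_fwd <- paste(he[, 1], he[, 2])
  key_rev <- paste(he[, 2], he[, 1])
  # no duplicated directed edge, and every directed edge has its reverse
  !anyDuplicated(key_fwd) && all(key_fwd %in% key_rev)
}

#' @rdname is_watertight
#' @export
count_boundary_edges <- function(surface) {
  he <- half_edges(surface$faces)
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  sum(table(key) != 2)
}

#' @rdname is_watertight
#' @export
euler_characteristic <- function(surface) {
  he <- half_edges(surface$faces)
  key <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  nrow(surface$vertices) - length(unique(key)) + nrow(surface$faces)
}

#' Rigid transform of a surface
#'
#' @param surface A [tri_surface()].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation (mm).
#' @return Transformed `tri_surface`.
#' @export
transform_surface <- function(surface, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- surface$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  tri_surface(v, surface$faces)
}

#' Vertex normals (area-weighted, outward for consistently wound meshes)
#'
#' @param surface A [tri_surface()].
#' @return `n x 3` matrix of unit normals.
#' @export
vertex_normals <- function(surface) {
  fc <- face_corners(surface)
  fn <- cross3(fc$b - fc$a, fc$c - fc$a)  # area-weighted face normals
  vn <- matrix(0, nrow(surface$vertices), 3)
  for (k in 1:3) {
    idx <- surface$faces[, k]
    for (d in 1:3) vn[, d] <- vn[, d] + unname(tapply_add(fn[, d], idx, nrow(vn)))
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

# fast grouped sum into a length-n vector
tapply_add <- function(values, index, n) {
  out <- numeric(n)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Tidy a surface into a vertex tibble
#'
#' @param x A `tri_surface`.
#' @param ... Unused.
#' @return Tibble with one row per vertex (`vertex`, `x`, `y`, `z` in mm).
#' @method tidy tri_surface
#' @export
tidy.tri_surface <- function(x, ...) {
  v <- x$vertices
  tibble(vertex = seq_len(nrow(v)), x = v[, 1], y = v[, 2], z = v[, 3])
}

#' @method glance tri_surface
#' @export
glance.tri_surface <- function(x, ...) {
  tibble(n_vertices = nrow(x$vertices), n_faces = nrow(x$faces),
         area_mm2 = surface_area(x), watertight = is_watertight(x),
         euler_characteristic = euler_characteristic(x))
}

#' Read and write ASCII STL surfaces
#'
#' Minimal STL support for exchanging lumen surfaces. `read_stl()` welds
#' duplicated facet vertices (exact coordinate match after rounding to
#' `digits`).
#'
#' @param path File path.
#' @param surface A [tri_surface()].
#' @param name Solid name written to the header.
#' @param digits Rounding applied to coordinates when welding on read.
#' @return `read_stl()` a `tri_surface`; `write_stl()` the path, invisibly.
#' @export
write_stl <- function(surface, path, name = "pauhemo") {
  fc <- face_corners(surface)
  nrm <- cross3(fc$b - fc$a, fc$c - fc$a)
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  m <- nrow(surface$faces)
  blocks <- vapply(seq_len(m), function(i) {
    paste0(sprintf(" facet normal %.9g %.9g %.9g\n", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
           "  outer loop\n",
           sprintf("   vertex %.9g %.9g %.9g\n", fc$a[i, 1], fc$a[i, 2], fc$a[i, 3]),
           sprintf("   vertex %.9g %.9g %.9g\n", fc$b[i, 1], fc$b[i, 2], fc$b[i, 3]),
           sprintf("   vertex %.9g %.9g %.9g\n", fc$c[i, 1], fc$c[i, 2], fc$c[i, 3]),
           "  endloop\n endfacet")
  }, character(1))
  writeLines(blocks, con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path, digits = 6) {
  lines <- readLines(path)
  vlines <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vlines) %% 3 != 0) abort("Malformed STL: vertex count not a multiple of 3.")
  coords <- do.call(rbind, strsplit(trimws(vlines), "\\s+"))
  pts <- matrix(as.numeric(coords[, 2:4]), ncol = 3)
  key <- apply(round(pts, digits), 1, paste, collapse = ",")
  uid <- !duplicated(key)
  vmap <- match(key, key[uid])
  vertices <- pts[uid, , drop = FALSE]
  faces <- matrix(vmap, ncol = 3, byrow = TRUE)
  tri_surface(vertices, faces)
}
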