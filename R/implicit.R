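# Isosurface extraction by marching tetrahedra on a regular grid.
#
# Each grid cube is split into the six tetrahedra that share the main diagonal
# (000)-(111); this decomposition matches face diagonals across neighbouring
# cubes, so interpolated crossing points on shared edges coincide exactly and
# the extracted zero level set is watertight by construction. Triangle winding
# is fixed afterwards against the implicit-function gradient (outward = towards
# positive values; the convention is negative inside).

# local tetrahedron corners (cube corner bit codes 0..7, bits = x,y,z)
.mt_tets <- rbind(
  c(0L, 1L, 3L, 7L),
  c(0L, 1L, 5L, 7L),
  c(0L, 2L, 3L, 7L),
  c(0L, 2L, 6L, 7L),
  c(0L, 4L, 5L, 7L),
  c(0L, 4L, 6L, 7L)
)

# triangulation per sign code (bit i set <=> local vertex i inside).
# Each triangle is a triple of tet edges; an edge is c(a, b) in local 1..4.
.mt_cases <- local({
  e <- function(a, b) c(a, b)
  one <- function(v) {
    o <- setdiff(1:4, v)
    list(rbind(c(e(v, o[1]), e(v, o[2]), e(v, o[3]))))
  }
  two <- function(v1, v2) {
    o <- setdiff(1:4, c(v1, v2))
    # quad e(v1,o1) e(v1,o2) e(v2,o2) e(v2,o1)
    list(rbind(
      c(e(v1, o[1]), e(v1, o[2]), e(v2, o[2])),
      c(e(v1, o[1]), e(v2, o[2]), e(v2, o[1]))
    ))
  }
  cases <- vector("list", 14)
  cases[[1]] <- one(1)          # {1}
  cases[[2]] <- one(2)          # {2}
  cases[[3]] <- two(1, 2)       # {1,2}
  cases[[4]] <- one(3)          # {3}
  cases[[5]] <- two(1, 3)
  cases[[6]] <- two(2, 3)
  cases[[7]] <- one(4)          # complement {4}
  cases[[8]] <- one(4)          # {4}
  cases[[9]] <- two(1, 4)
  cases[[10]] <- two(2, 4)
  cases[[11]] <- one(3)         # complement {3}
  cases[[12]] <- two(3, 4)
  cases[[13]] <- one(2)         # complement {2}
  cases[[14]] <- one(1)         # complement {1}
  cases
})

#' Extract the zero isosurface of an implicit function
#'
#' Polygonises `{x : f(x) = 0}` (negative inside) over a regular grid by
#' marching tetrahedra. The result is a closed, manifold, consistently
#' outward-oriented triangulation provided the surface stays strictly inside
#' the grid box.
#'
#' @param f Vectorised implicit function: takes an `n x 3` matrix of points
#'   (mm) and returns `n` signed values, negative inside the solid.
#' @param xs,ys,zs Strictly increasing grid coordinate vectors (mm).
#' @return A [tri_surface()].
#' @export
marching_tets <- function(f, xs, ys, zs) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  if (min(nx, ny, nz) < 2) abort("Grid needs at least 2 points per axis.")
  h <- min(diff(xs)[1], diff(ys)[1], diff(zs)[1])

  n_nodes <- nx * ny * nz
  vals <- numeric(n_nodes)
  idx_all <- seq_len(n_nodes)
  node_xyz <- function(ids) {
    i <- (ids - 1L) %% nx + 1L
    j <- ((ids - 1L) %/% nx) %% ny + 1L
    k <- (ids - 1L) %/% (nx * ny) + 1L
    cbind(xs[i], ys[j], zs[k])
  }
  chunk <- 500000L
  for (s in seq(1L, n_nodes, by = chunk)) {
    e <- min(s + chunk - 1L, n_nodes)
    vals[s:e] <- f(node_xyz(s:e))
  }
  vals[vals == 0] <- 1e-12  # nudge exact zeros outside

  inside <- vals < 0
  # cubes with mixed corner signs
  bi <- rep(seq_len(nx - 1L), times = (ny - 1L) * (nz - 1L))
  bj <- rep(rep(seq_len(ny - 1L), each = nx - 1L), times = nz - 1L)
  bk <- rep(seq_len(nz - 1L), each = (nx - 1L) * (ny - 1L))
  base <- bi + (bj - 1L) * nx + (bk - 1L) * nx * ny
  off <- function(dx, dy, dz) dx + dy * nx + dz * nx * ny
  offs <- c(off(0L, 0L, 0L), off(1L, 0L, 0L), off(0L, 1L, 0L), off(1L, 1L, 0L),
            off(0L, 0L, 1L), off(1L, 0L, 1L), off(0L, 1L, 1L), off(1L, 1L, 1L))
  cnt <- integer(length(base))
  for (o in offs) cnt <- cnt + inside[base + o]
  base <- base[cnt > 0L & cnt < 8L]
  if (length(base) == 0) abort("Implicit surface does not intersect the grid.")

  tri_a <- list(); tri_b <- list(); p <- 0L
  for (t in seq_len(nrow(.mt_tets))) {
    loc <- .mt_tets[t, ]
    g <- cbind(base + offs[loc[1] + 1L], base + offs[loc[2] + 1L],
               base + offs[loc[3] + 1L], base + offs[loc[4] + 1L])
    ins <- matrix(inside[g], ncol = 4)
    code <- ins[, 1] + 2L * ins[, 2] + 4L * ins[, 3] + 8L * ins[, 4]
    for (cc in 1:14) {
      sel <- which(code == cc)
      if (length(sel) == 0) next
      tris <- .mt_cases[[cc]][[1]]
      for (r in seq_len(nrow(tris))) {
        ed <- tris[r, ]  # a1 b1 a2 b2 a3 b3 (local ids)
        p <- p + 1L
        tri_a[[p]] <- cbind(g[sel, ed[1]], g[sel, ed[3]], g[sel, ed[5]])
        tri_b[[p]] <- cbind(g[sel, ed[2]], g[sel, ed[4]], g[sel, ed[6]])
      }
    }
  }
  A <- do.call(rbind, tri_a)  # ntri x 3 of edge endpoint a (node ids)
  B <- do.call(rbind, tri_b)

  # unique crossing edges -> interpolated vertices
  lo <- pmin(A, B); hi <- pmax(A, B)
  key <- paste(as.vector(lo), as.vector(hi))
  uid <- which(!duplicated(key))
  vmap <- match(key, key[uid])
  ea <- as.vector(lo)[uid]; eb <- as.vector(hi)[uid]
  fa <- vals[ea]; fb <- vals[eb]
  tt <- fa / (fa - fb)
  pa <- node_xyz(ea); pb <- node_xyz(eb)
  verts <- pa + tt * (pb - pa)
  faces <- matrix(vmap, ncol = 3)

  orient_faces_consistently(verts, faces)
}

# Make triangle winding consistent by propagating orientation across shared
# edges (each undirected edge must be traversed in opposite directions by its
# two faces), then pick the global outward orientation by signed volume.
orient_faces_consistently <- function(verts, faces) {
  m <- nrow(faces)
  he <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  face_of <- rep(seq_len(m), times = 3)
  fwd <- he[, 1] < he[, 2]
  ekey <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  eid <- match(ekey, unique(ekey))
  nE <- max(eid)
  f1 <- integer(nE); f2 <- integer(nE)
  d1 <- logical(nE); d2 <- logical(nE)
  first <- !duplicated(eid)
  f1[eid[first]] <- face_of[first]; d1[eid[first]] <- fwd[first]
  second <- duplicated(eid)
  f2[eid[second]] <- face_of[second]; d2[eid[second]] <- fwd[second]

  fedges <- matrix(eid, ncol = 3)          # m x 3 edge ids per face
  flipped <- logical(m)
  visited <- logical(m)
  stack <- integer(m); top <- 0L
  for (s0 in seq_len(m)) {
    if (visited[s0]) next
    visited[s0] <- TRUE
    top <- 1L; stack[1] <- s0
    while (top > 0L) {
      fc <- stack[top]; top <- top - 1L
      for (k in 1:3) {
        e <- fedges[fc, k]
        g <- if (f1[e] == fc) f2[e] else f1[e]
        if (g == 0L || visited[g]) next
        df <- if (f1[e] == fc) d1[e] else d2[e]
        dg <- if (f1[e] == g) d1[e] else d2[e]
        # opposite traversal required after accounting for flips
        flipped[g] <- xor(df, flipped[fc]) == xor(dg, FALSE)
        visited[g] <- TRUE
        top <- top + 1L; stack[top] <- g
      }
    }
  }
  faces[flipped, ] <- faces[flipped, c(1, 3, 2), drop = FALSE]
  orient_outward(tri_surface(verts, faces))
}
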