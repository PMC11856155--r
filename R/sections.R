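# Planar cross-sections of a triangulated lumen: plane-mesh intersection,
# loop chaining, and the per-section metrics (area, maximum diameter).

# Intersect the surface with the plane through `origin` with unit `normal`.
# Returns a list of closed loops, each an ordered k x 3 matrix of points.
plane_mesh_loops <- function(surface, origin, normal) {
  v <- surface$vertices
  f <- surface$faces
  normal <- unit3(normal)
  d <- as.vector((v - matrix(origin, nrow(v), 3, byrow = TRUE)) %*% normal)
  d[d == 0] <- 1e-12
  side <- d > 0
  s1 <- side[f[, 1]]; s2 <- side[f[, 2]]; s3 <- side[f[, 3]]
  crossing <- which((s1 != s2) | (s2 != s3))
  if (length(crossing) == 0) return(list())

  edge_point_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  seg_a <- character(length(crossing)); seg_b <- character(length(crossing))
  pts_env <- new.env(parent = emptyenv())
  add_pt <- function(i, j) {
    key <- edge_point_key(i, j)
    if (is.null(pts_env[[key]])) {
      t <- d[i] / (d[i] - d[j])
      pts_env[[key]] <- v[i, ] + t * (v[j, ] - v[i, ])
    }
    key
  }
  for (q in seq_along(crossing)) {
    tri <- f[crossing[q], ]
    ss <- side[tri]
    # the lone vertex on one side determines the two crossing edges
    lone <- if (sum(ss) == 1) which(ss) else which(!ss)
    others <- setdiff(1:3, lone)
    seg_a[q] <- add_pt(tri[lone], tri[others[1]])
    seg_b[q] <- add_pt(tri[lone], tri[others[2]])
  }

  # chain segments into closed loops: each crossing point joins exactly two
  # segments on a closed manifold
  nseg <- length(seg_a)
  keys <- unique(c(seg_a, seg_b))
  ia <- match(seg_a, keys); ib <- match(seg_b, keys)
  inc <- vector("list", length(keys))
  for (q in seq_len(nseg)) {
    inc[[ia[q]]] <- c(inc[[ia[q]]], q)
    inc[[ib[q]]] <- c(inc[[ib[q]]], q)
  }
  used <- logical(nseg)
  loops <- list()
  for (q0 in seq_len(nseg)) {
    if (used[q0]) next
    path <- ia[q0]
    q <- q0
    node <- ia[q0]
    closed <- FALSE
    repeat {
      used[q] <- TRUE
      nxt_node <- if (ia[q] == node) ib[q] else ia[q]
      if (nxt_node == path[1]) {
        closed <- TRUE
        break
      }
      path <- c(path, nxt_node)
      cand <- inc[[nxt_node]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break  # open chain (boundary/hole): drop
      node <- nxt_node
      q <- cand[1]
    }
    if (closed && length(path) >= 3) {
      loops[[length(loops) + 1]] <-
        do.call(rbind, lapply(keys[path], function(k) pts_env[[k]]))
    }
  }
  loops
}

# algebraic (Kasa) least-squares circle fit; returns center and radius
fit_circle_2d <- function(xy) {
  A <- cbind(2 * xy[, 1], 2 * xy[, 2], 1)
  b <- xy[, 1]^2 + xy[, 2]^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (r2 <= 0) return(NULL)
  list(center = sol[1:2], radius = sqrt(r2))
}

# robust lumen-center estimate in a cut plane: fit a circle to the section
# perimeter around the query point, discarding perimeter arcs (branch ostia,
# neighbouring vessels) that do not belong to the local lumen circle
lumen_center_2d <- function(xy, r_expected = NULL, clip_factor = 1.45,
                            resid_tol = c(0.3, 0.2, 0.15, 0.12)) {
  d0 <- sqrt(rowSums(xy^2))  # query point is the plane origin
  r0 <- r_expected %||% stats::median(d0)
  keep <- d0 < clip_factor * r0
  if (sum(keep) < 8) keep <- rep(TRUE, nrow(xy))
  fit <- fit_circle_2d(xy[keep, , drop = FALSE])
  if (is.null(fit)) return(NULL)
  for (tol in resid_tol) {
    resid <- abs(sqrt(rowSums(sweep(xy, 2, fit$center)^2)) - fit$radius)
    keep <- resid < tol * fit$radius
    if (sum(keep) < 8) break
    fit2 <- fit_circle_2d(xy[keep, , drop = FALSE])
    if (is.null(fit2)) break
    fit <- fit2
  }
  # a fit much larger than the expected lumen means the cut is dominated by a
  # merged neighbouring structure: report failure so the caller can coast
  if (fit$radius > 1.6 * r0 || sqrt(sum(fit$center^2)) > r0) return(NULL)
  c(fit$center, fit$radius)
}

# plane basis orthogonal to the (unit) normal
plane_basis <- function(normal) {
  ref <- diag(3)[which.min(abs(normal)), ]
  e1 <- unit3(ref - normal * sum(ref * normal))
  e2 <- pracma_cross(normal, e1)
  list(e1 = e1, e2 = e2)
}

polygon_area_centroid_2d <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) {
    list(area = 0, centroid = colMeans(xy))
  } else {
    cx <- sum((x + xn) * cr) / (6 * a)
    cy <- sum((y + yn) * cr) / (6 * a)
    list(area = abs(a), centroid = c(cx, cy))
  }
}

# nearest closed section of the cut plane: polygon, area (mm^2), centroid (3D)
section_at_plane <- function(surface, origin, normal, near_point = origin) {
  loops <- plane_mesh_loops(surface, origin, normal)
  if (length(loops) == 0) return(NULL)
  dists <- vapply(loops, function(L) {
    min(sqrt(rowSums((L - matrix(near_point, nrow(L), 3, byrow = TRUE))^2)))
  }, numeric(1))
  loop <- loops[[which.min(dists)]]
  normal <- unit3(normal)
  bb <- plane_basis(normal)
  rel <- loop - matrix(origin, nrow(loop), 3, byrow = TRUE)
  xy <- cbind(rel %*% bb$e1, rel %*% bb$e2)
  ac <- polygon_area_centroid_2d(xy)
  centroid3 <- origin + ac$centroid[1] * bb$e1 + ac$centroid[2] * bb$e2
  list(polygon = loop, polygon_2d = xy, area = ac$area, centroid = centroid3,
       normal = normal, origin = origin)
}

# resample a closed polygon perimeter at spacing <= ds (mm)
resample_polygon <- function(xy, ds = 0.2) {
  closed <- rbind(xy, xy[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  keep <- c(TRUE, seg > 1e-12)  # drop coincident consecutive points
  closed <- closed[keep, , drop = FALSE]
  seg <- seg[seg > 1e-12]
  s <- c(0, cumsum(seg))
  L <- tail(s, 1)
  n <- max(nrow(xy), ceiling(L / ds))
  ss <- seq(0, L, length.out = n + 1)[seq_len(n)]
  cbind(approx(s, closed[, 1], ss)$y, approx(s, closed[, 2], ss)$y)
}

# maximum pairwise distance over a planar polygon, after perimeter resampling
# (convex hull first: the diameter is attained on the hull)
polygon_dmax <- function(xy, ds = 0.2) {
  r <- resample_polygon(xy, ds)
  h <- r[grDevices::chull(r), , drop = FALSE]
  if (nrow(h) < 2) return(0)
  d2 <- outer(h[, 1], h[, 1], "-")^2 + outer(h[, 2], h[, 2], "-")^2
  sqrt(max(d2))
}

#' Extract cross-sections along a centerline
#'
#' Cuts the surface with planes orthogonal to the local centerline tangent at
#' uniformly spaced stations, keeps the closed intersection loop nearest the
#' centerline point, and measures the planar polygon: area by the shoelace
#' formula (reported in cm^2) and maximum diameter as the largest pairwise
#' vertex distance after perimeter resampling at `dmax_resample_mm`
#' (reported in cm).
#'
#' @param surface A [tri_surface()].
#' @param cl A [centerline()].
#' @param s_start,s_end Arc-length range (mm) along `cl`.
#' @param spacing Station spacing (mm).
#' @param dmax_resample_mm Perimeter resampling step for the diameter search.
#' @return A `cross_sections` tibble with columns `station_mm`, `area_cm2`,
#'   `dmax_cm` and list-columns `polygon` (k x 3 mm), `origin`, `normal`.
#'   Stations where the cut is open (mesh hole) are skipped with a warning.
#' @export
extract_sections <- function(surface, cl, s_start = 0, s_end = NULL,
                             spacing = 1, dmax_resample_mm = 0.2) {
  L <- cl_length(cl)
  s_end <- s_end %||% L
  if (s_start < 0 || s_end > L + 1e-9 || s_start >= s_end) {
    abort(sprintf("Station range [%.1f, %.1f] mm outside centerline length %.1f mm.",
                  s_start, s_end, L))
  }
  stations <- seq(s_start, s_end, by = spacing)
  rows <- list()
  skipped <- 0
  for (s in stations) {
    o <- cl_point_at(cl, s)
    nrm <- cl_tangent_at(cl, s)
    sec <- section_at_plane(surface, o, nrm, near_point = o)
    if (is.null(sec) || sec$area <= 0) {
      skipped <- skipped + 1
      next
    }
    rows[[length(rows) + 1]] <- tibble(
      station_mm = s,
      area_cm2 = sec$area / 100,          # mm^2 -> cm^2
      dmax_cm = polygon_dmax(sec$polygon_2d, dmax_resample_mm) / 10,  # mm -> cm
      polygon = list(sec$polygon),
      origin = list(o),
      normal = list(sec$normal)
    )
  }
  if (skipped > 0) {
    warn(sprintf("%d station(s) had no closed section (open cut) and were skipped.", skipped))
  }
  if (length(rows) == 0) abort("No closed cross-sections found in the requested range.")
  out <- bind_rows(rows)
  class(out) <- c("cross_sections", class(out))
  out
}

#' Write per-branch section profiles as CSV (`station_mm,area_cm2,dmax_cm`)
#'
#' @param sections A `cross_sections` tibble from [extract_sections()].
#' @param path Output CSV path.
#' @export
write_sections_csv <- function(sections, path) {
  utils::write.csv(
    data.frame(station_mm = sections$station_mm,
               area_cm2 = sections$area_cm2,
               dmax_cm = sections$dmax_cm),
    path, row.names = FALSE)
  invisible(path)
}
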