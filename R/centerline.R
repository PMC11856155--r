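#' Lumen centerlines
#'
#' A `centerline` is an ordered 3D polyline through the lumen center, stored
#' as a tibble with coordinates in mm (`x`, `y`, `z`) and cumulative arc
#' length `s_mm`, plus a `label` attribute (e.g. `"AO"`, `"LSA"`).
#'
#' @param points `n x 3` matrix of polyline points (mm), `n >= 2`.
#' @param label Character label.
#' @return A `centerline` tibble.
#' @export
centerline <- function(points, label = "centerline") {
  points <- as.matrix(points)
  if (nrow(points) < 2) abort("A centerline needs at least 2 points.")
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg == 0)) {
    keep <- c(TRUE, seg > 0)
    points <- points[keep, , drop = FALSE]
    seg <- sqrt(rowSums(diff(points)^2))
  }
  out <- tibble(x = points[, 1], y = points[, 2], z = points[, 3],
                s_mm = c(0, cumsum(seg)))
  structure(out, label = label, class = c("centerline", class(out)))
}

cl_points <- function(cl) cbind(cl$x, cl$y, cl$z)
cl_length <- function(cl) tail(cl$s_mm, 1)
cl_label <- function(cl) attr(cl, "label") %||% "centerline"

#' Point and tangent at a given arc length
#'
#' @param cl A [centerline()].
#' @param s Arc length (mm) within `[0, cl_length]`.
#' @return `cl_point_at()` a length-3 point; `cl_tangent_at()` a unit tangent.
#' @export
cl_point_at <- function(cl, s) {
  if (s < -1e-9 || s > cl_length(cl) + 1e-9) {
    abort(sprintf("Arc length %.2f mm outside centerline '%s' (length %.2f mm).",
                  s, cl_label(cl), cl_length(cl)))
  }
  c(approx(cl$s_mm, cl$x, s, rule = 2)$y,
    approx(cl$s_mm, cl$y, s, rule = 2)$y,
    approx(cl$s_mm, cl$z, s, rule = 2)$y)
}

#' @rdname cl_point_at
#' @param h Step used for the central difference (mm).
#' @export
cl_tangent_at <- function(cl, s, h = NULL) {
  L <- cl_length(cl)
  h <- h %||% min(1, L / 20)
  p1 <- cl_point_at(cl, max(0, s - h))
  p2 <- cl_point_at(cl, min(L, s + h))
  unit3(p2 - p1)
}

#' Resample a centerline at uniform arc-length spacing
#'
#' @param cl A [centerline()].
#' @param step Target spacing (mm).
#' @return A `centerline`.
#' @export
resample_centerline <- function(cl, step = 1) {
  L <- cl_length(cl)
  s <- seq(0, L, length.out = max(2, ceiling(L / step) + 1))
  centerline(cbind(approx(cl$s_mm, cl$x, s)$y,
                   approx(cl$s_mm, cl$y, s)$y,
                   approx(cl$s_mm, cl$z, s)$y), label = cl_label(cl))
}

# moving-average smoothing preserving endpoints
smooth_centerline <- function(cl, window = 5) {
  p <- cl_points(cl)
  n <- nrow(p)
  if (n <= window) return(cl)
  half <- window %/% 2
  sm <- p
  for (i in seq_len(n)) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    sm[i, ] <- colMeans(p[lo:hi, , drop = FALSE])
  }
  sm[1, ] <- p[1, ]; sm[n, ] <- p[n, ]
  centerline(sm, label = cl_label(cl))
}

#' Centerline tortuosity
#'
#' Tortuosity index of a centerline: arc length over straight endpoint
#' distance, minus one (`index = "excess"`, the default, 0 for a straight
#' segment) or the raw ratio (`index = "ratio"`).
#'
#' @param cl A [centerline()].
#' @param index `"excess"` for `L/chord - 1`, `"ratio"` for `L/chord`.
#' @return Dimensionless tortuosity.
#' @export
tortuosity <- function(cl, index = c("excess", "ratio")) {
  index <- match.arg(index)
  p <- cl_points(cl)
  chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  if (chord < 1e-9) abort("Centerline endpoints coincide; tortuosity undefined.")
  r <- cl_length(cl) / chord
  if (index == "excess") r - 1 else r
}

#' Extract a lumen centerline by centroid marching
#'
#' Marches a cut plane through the lumen: at each step the plane orthogonal to
#' the current direction is intersected with the surface, the point is moved
#' to the area centroid of the nearest closed section, and the front advances
#' by `step` along the (smoothed) direction of travel. The result is resampled
#' uniformly and smoothed with a short moving average.
#'
#' @param surface A [tri_surface()].
#' @param seed_point Point inside the lumen where the march starts (mm).
#' @param target_point Approximate end point; the march stops once it is
#'   reached within one step (the approximate target itself is not appended).
#' @param step March step (mm).
#' @param initial_direction Optional starting direction; defaults to
#'   `target_point - seed_point`.
#' @param label Label for the resulting centerline.
#' @param smooth_window Moving-average window (samples) for final smoothing.
#' @param max_iter Iteration cap; exceeding it aborts with a diagnostic.
#' @param r_hint Expected lumen radius at the seed (mm); steadies the robust
#'   recentring before a running estimate is available.
#' @return A [centerline()].
#' @export
compute_centerline <- function(surface, seed_point, target_point, step = 2,
                               initial_direction = NULL, label = "centerline",
                               smooth_window = 5, max_iter = NULL,
                               r_hint = NULL) {
  seed_point <- as.numeric(seed_point)
  target_point <- as.numeric(target_point)
  dir <- unit3(initial_direction %||% (target_point - seed_point))
  max_iter <- max_iter %||% ceiling(4 * pi * sqrt(sum((target_point - seed_point)^2)) / step + 50)

  p <- seed_point
  pts <- list()
  prev <- NULL
  radii <- numeric(0)
  for (it in seq_len(max_iter)) {
    sec <- section_at_plane(surface, p, dir, near_point = p)
    if (is.null(sec)) {
      abort(sprintf(paste0("Centroid marching exited the surface near ",
                           "(%.1f, %.1f, %.1f) after %d steps."),
                    p[1], p[2], p[3], it - 1))
    }
    # robust recentring: fit a circle to the section perimeter (resampled for
    # uniform density) so branch ostia crossing the cut plane cannot drag the
    # front off the lumen axis
    per <- resample_polygon(sec$polygon_2d, ds = 0.5)
    r_exp <- if (length(radii)) stats::median(tail(radii, 5)) else r_hint
    cf <- lumen_center_2d(per, r_expected = r_exp)
    if (is.null(cf)) {
      ctr <- p  # cut dominated by a branch ostium: coast along `dir`
    } else {
      bb <- plane_basis(unit3(dir))
      ctr <- p + cf[1] * bb$e1 + cf[2] * bb$e2
      radii <- c(radii, cf[3])
    }
    if (!is.null(prev) && sqrt(sum((ctr - prev)^2)) > 4 * step + 1e-9) {
      abort(sprintf("Centroid marching jumped %.1f mm at step %d; section tracking lost.",
                    sqrt(sum((ctr - prev)^2)), it))
    }
    pts[[length(pts) + 1]] <- ctr
    if (!is.null(prev) && sqrt(sum((ctr - prev)^2)) > 1e-9) {
      dir_new <- unit3(ctr - prev)
      dir <- unit3(0.5 * dir + 0.5 * dir_new)
    }
    prev <- ctr
    to_target <- target_point - ctr
    dist_t <- sqrt(sum(to_target^2))
    if (dist_t <= step || (dist_t <= 10 * step && sum(to_target * dir) < 0)) break
    if (it == max_iter) {
      abort(sprintf("Centroid marching failed to reach the target within %d steps.", max_iter))
    }
    p <- ctr + step * dir
  }
  if (length(pts) < 2) abort("Centroid marching produced fewer than 2 points.")
  cl <- centerline(do.call(rbind, pts), label = label)
  cl <- resample_centerline(cl, step = min(step, 1))
  smooth_centerline(cl, window = smooth_window)
}

#' @method glance centerline
#' @export
glance.centerline <- function(x, ...) {
  tibble(label = cl_label(x), n_points = nrow(x), length_mm = cl_length(x),
         tortuosity = tortuosity(x))
}
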