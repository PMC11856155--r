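#' Wall-shear-stress vector time series
#'
#' A `wss_series` carries per-node WSS vectors (Pa) over one cardiac cycle on a
#' [tri_surface()]: an `n_nodes x n_steps x 3` array sampled uniformly at
#' `dt = T / n_steps` with `t` in `[0, T)`. Time integrals use the periodic
#' trapezoidal rule, which for uniform full-period sampling equals
#' `dt * sum(samples)`.
#'
#' @param surface A [tri_surface()].
#' @param values Numeric array `n_nodes x n_steps x 3` of WSS vectors (Pa).
#' @param period Cycle duration T (s).
#' @return A `wss_series` object.
#' @export
wss_series <- function(surface, values, period) {
  if (!is_tri_surface(surface)) abort("`surface` must be a tri_surface.")
  d <- dim(values)
  if (length(d) != 3 || d[3] != 3) abort("`values` must be an n x steps x 3 array.")
  if (d[1] != nrow(surface$vertices)) {
    abort("First dimension of `values` must match the number of surface vertices.")
  }
  if (!all(is.finite(values))) abort("WSS values must be finite.")
  if (period <= 0) abort("`period` must be positive.")
  structure(list(surface = surface, values = values, period = period,
                 n_steps = d[2], dt = period / d[2]),
            class = "wss_series")
}

#' @export
print.wss_series <- function(x, ...) {
  cat(sprintf("<wss_series: %d nodes x %d steps, T = %g s>\n",
              dim(x$values)[1], x$n_steps, x$period))
  invisible(x)
}

#' Synthesise a WSS field with known TAWSS/OSI ground truth
#'
#' Builds, per surface node, the tangential signal
#' `WSS(t) = m * ((1 - alpha) + alpha * sq(t)) * d` where `d` is a unit tangent
#' direction, `m` a magnitude (Pa) and `sq(t)` a square wave equal to +1 over
#' the first half of the cycle and -1 over the second. `alpha` in `[0, 1]` is
#' the reversal fraction: `alpha = 0` gives a steady direction (OSI 0) and
#' `alpha = 1` a perfect equal-duration reversal (OSI 0.5). Analytic
#' ground-truth indicator values are attached as attributes `truth_tawss` and
#' `truth_osi`.
#'
#' @param surface A [tri_surface()].
#' @param base_magnitude Either a single magnitude in Pa or a function of the
#'   `n x 3` vertex matrix returning per-node magnitudes.
#' @param oscillation Either a single reversal fraction in `[0, 1]` or a
#'   function of the vertex matrix returning per-node fractions.
#' @param period Cycle duration (s).
#' @param n_steps Even number of time samples per cycle, at least 8.
#' @param noise Relative uniform jitter applied to per-node magnitudes
#'   (accounted for in the ground truth).
#' @param seed Integer seed for the jitter.
#' @return A [wss_series()] with `truth_tawss` / `truth_osi` attributes.
#' @export
make_wss_field <- function(surface, base_magnitude = 1.5, oscillation = 0.2,
                           period = 0.85, n_steps = 32, noise = 0.05, seed = 1L) {
  if (n_steps < 8) abort("`n_steps` must be at least 8.")
  if (n_steps %% 2 != 0) abort("`n_steps` must be even (equal-duration reversal halves).")
  v <- surface$vertices
  n <- nrow(v)
  m <- if (is.function(base_magnitude)) base_magnitude(v) else rep(base_magnitude, n)
  alpha <- if (is.function(oscillation)) oscillation(v) else rep(oscillation, n)
  if (any(m < 0)) abort("Base magnitudes must be non-negative.")
  if (any(alpha < 0 | alpha > 1)) abort("Oscillation fractions must lie in [0, 1].")
  if (noise > 0) {
    rng <- local({ set.seed(seed); stats::runif(n, -1, 1) })
    m <- m * (1 + noise * rng)
  }

  # unit tangent direction per node: project the global axis least aligned
  # with the normal onto the tangent plane
  nrm <- vertex_normals(surface)
  ref <- diag(3)[max.col(-abs(nrm)), , drop = FALSE]
  d <- ref - nrm * rowSums(ref * nrm)
  len <- sqrt(rowSums(d^2)); len[len == 0] <- 1
  d <- d / len

  sq <- rep(c(1, -1), each = n_steps / 2)
  vals <- array(0, dim = c(n, n_steps, 3))
  for (k in seq_len(n_steps)) {
    amp <- m * ((1 - alpha) + alpha * sq[k])
    vals[, k, ] <- d * amp
  }
  out <- wss_series(surface, vals, period)
  mean_abs <- m * (1 + abs(1 - 2 * alpha)) / 2
  mean_signed <- m * (1 - alpha)
  truth_osi <- ifelse(mean_abs > 0, 0.5 * (1 - mean_signed / mean_abs), NA_real_)
  attr(out, "truth_tawss") <- mean_abs
  attr(out, "truth_osi") <- truth_osi
  out
}

#' Tidy a WSS series into a long tibble
#'
#' @param x A [wss_series()].
#' @param ... Unused.
#' @return Tibble with columns `vertex`, `t_s`, `wss_x/y/z`, `magnitude`.
#' @method tidy wss_series
#' @export
tidy.wss_series <- function(x, ...) {
  n <- dim(x$values)[1]
  steps <- x$n_steps
  tibble(
    vertex = rep(seq_len(n), times = steps),
    t_s = rep((seq_len(steps) - 1) * x$dt, each = n),
    wss_x = as.vector(x$values[, , 1]),
    wss_y = as.vector(x$values[, , 2]),
    wss_z = as.vector(x$values[, , 3]),
    magnitude = as.vector(sqrt(x$values[, , 1]^2 + x$values[, , 2]^2 + x$values[, , 3]^2))
  )
}

#' Write / read a WSS series as plain-text point-data tables
#'
#' The on-disk form is a whitespace-separated table with one row per node and
#' columns `WSS_t<k>_x/_y/_z` for each time step, plus a JSON sidecar holding
#' the period and step count.
#'
#' @param series A [wss_series()].
#' @param path Output data file; the sidecar is written as `<path>.json`.
#' @param surface Surface to attach on read.
#' @return `read_wss_series()` a `wss_series`; the writer returns `path`.
#' @export
write_wss_series <- function(series, path) {
  steps <- series$n_steps
  cols <- lapply(seq_len(steps), function(k) {
    m <- series$values[, k, ]
    colnames(m) <- sprintf("WSS_t%d_%s", k - 1, c("x", "y", "z"))
    m
  })
  tab <- do.call(cbind, cols)
  utils::write.table(tab, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(period_s = series$period, n_steps = steps),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_wss_series
#' @export
read_wss_series <- function(path, surface) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  tab <- as.matrix(read.table(path, header = TRUE))
  steps <- meta$n_steps
  n <- nrow(tab)
  vals <- array(0, dim = c(n, steps, 3))
  for (k in seq_len(steps)) {
    vals[, k, ] <- tab[, sprintf("WSS_t%d_%s", k - 1, c("x", "y", "z"))]
  }
  wss_series(surface, vals, meta$period_s)
}
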