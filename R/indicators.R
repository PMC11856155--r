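#' Wall-shear-stress indicators: TAWSS, OSI, ECAP
#'
#' Per-node indicators over one cardiac cycle from a WSS vector time series.
#' Integrals use the periodic trapezoidal rule (equivalent to `dt * sum` for
#' uniform full-period sampling):
#'
#' * TAWSS = `(1/T) * integral |WSS| dt` (Pa);
#' * OSI = `0.5 * (1 - |integral WSS dt| / integral |WSS| dt)`, in
#'   `[0, 0.5]`: 0 for a fixed direction, 0.5 for perfect equal-duration
#'   reversal. Nodes with `integral |WSS| dt` below `mag_floor` are masked
#'   (`NA`);
#' * ECAP = OSI / TAWSS (Pa^-1), masked where TAWSS is below `tawss_floor`.
#'
#' @param series A [wss_series()].
#' @param mag_floor Floor on the magnitude integral (Pa s) below which OSI is
#'   masked.
#' @return Numeric vector, one value per surface node (`NA` where masked).
#' @name wss_indicators
NULL

wss_magnitude <- function(series) {
  sqrt(series$values[, , 1]^2 + series$values[, , 2]^2 + series$values[, , 3]^2)
}

#' @rdname wss_indicators
#' @export
compute_tawss <- function(series) {
  rowMeans(wss_magnitude(series))  # (dt * sum) / T = mean
}

#' @rdname wss_indicators
#' @export
compute_osi <- function(series, mag_floor = 1e-12) {
  mx <- rowMeans(series$values[, , 1])
  my <- rowMeans(series$values[, , 2])
  mz <- rowMeans(series$values[, , 3])
  num <- sqrt(mx^2 + my^2 + mz^2) * series$period
  den <- rowMeans(wss_magnitude(series)) * series$period
  osi <- 0.5 * (1 - num / den)
  osi[den < mag_floor] <- NA_real_
  osi
}

#' @rdname wss_indicators
#' @param tawss,osi Per-node vectors from [compute_tawss()]/[compute_osi()].
#' @param tawss_floor TAWSS floor (Pa) below which ECAP is masked.
#' @export
compute_ecap <- function(tawss, osi, tawss_floor = 1e-6) {
  if (length(tawss) != length(osi)) abort("`tawss` and `osi` must be aligned.")
  ecap <- osi / tawss
  ecap[!is.na(tawss) & tawss < tawss_floor] <- NA_real_
  ecap
}

#' All indicator maps for a WSS series
#'
#' @param series A [wss_series()].
#' @param tawss_floor,mag_floor Masking floors (see [compute_ecap()],
#'   [compute_osi()]).
#' @return An `indicator_maps` tibble: `vertex`, `tawss`, `osi`, `ecap`,
#'   `valid` (TRUE where no mask applied), with the surface attached as an
#'   attribute.
#' @export
indicator_maps <- function(series, tawss_floor = 1e-6, mag_floor = 1e-12) {
  tawss <- compute_tawss(series)
  osi <- compute_osi(series, mag_floor = mag_floor)
  ecap <- compute_ecap(tawss, osi, tawss_floor = tawss_floor)
  out <- tibble(vertex = seq_along(tawss), tawss = tawss, osi = osi,
                ecap = ecap, valid = !is.na(osi) & !is.na(ecap))
  structure(out, surface = series$surface,
            class = c("indicator_maps", class(out)))
}

#' Surface area fraction exposed beyond a threshold
#'
#' Classifies each triangle by the mean of its vertex values (strict
#' inequality against the threshold; ties excluded) and reports the
#' classified triangle area as a percentage of the total area of triangles
#' with defined (non-masked) values.
#'
#' @param values Per-node vector aligned with `surface` (NA = masked).
#' @param surface A [tri_surface()].
#' @param threshold Threshold value.
#' @param direction `"below"` or `"above"`.
#' @return Percentage in `[0, 100]`.
#' @export
exposed_area <- function(values, surface, threshold,
                         direction = c("below", "above")) {
  direction <- match.arg(direction)
  if (length(values) != nrow(surface$vertices)) {
    abort("`values` must have one entry per surface vertex.")
  }
  f <- surface$faces
  tri_mean <- (values[f[, 1]] + values[f[, 2]] + values[f[, 3]]) / 3
  areas <- triangle_areas(surface)
  ok <- !is.na(tri_mean)
  total <- sum(areas[ok])
  if (total == 0) return(NA_real_)
  pass <- if (direction == "below") tri_mean < threshold else tri_mean > threshold
  100 * sum(areas[ok & pass]) / total
}

#' Exposure report (thresholded-area statistics)
#'
#' Area fraction with TAWSS below `tawss_threshold` (default 0.4 Pa,
#' atherosclerosis-prone) and with OSI above `osi_threshold` (default 0.25,
#' atherogenic), each normalised to the wall area with defined values.
#'
#' @param maps An [indicator_maps()] tibble.
#' @param tawss_threshold TAWSS threshold (Pa).
#' @param osi_threshold OSI threshold.
#' @return Tibble: `area_low_tawss_pct`, `area_high_osi_pct`, `total_area_m2`.
#' @export
exposure_report <- function(maps, tawss_threshold = 0.4, osi_threshold = 0.25) {
  surface <- attr(maps, "surface")
  tibble(
    area_low_tawss_pct = exposed_area(maps$tawss, surface, tawss_threshold, "below"),
    area_high_osi_pct = exposed_area(maps$osi, surface, osi_threshold, "above"),
    total_area_m2 = mm2_to_m2(surface_area(surface))
  )
}

#' @method glance indicator_maps
#' @export
glance.indicator_maps <- function(x, ...) {
  dplyr::bind_cols(
    exposure_report(x),
    tibble(mean_tawss_Pa = mean(x$tawss, na.rm = TRUE),
           mean_osi = mean(x$osi, na.rm = TRUE),
           max_ecap_Pa_inv = max(x$ecap, na.rm = TRUE),
           n_masked = sum(!x$valid))
  )
}
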