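#' Periodic inlet flow waveforms
#'
#' `flow_waveform()` wraps one cardiac cycle of volumetric flow as a tibble
#' with columns `t_s` (s, in `[0, T)`, uniformly spaced) and `q_mL_s` (mL/s).
#' `make_waveform()` builds a parametric aortic inflow: a half-sine systolic
#' ejection followed by a brief early-diastolic reversal, scaled so that the
#' periodic trapezoidal integral of the returned samples equals the stroke
#' volume exactly.
#'
#' @param times Sample times in seconds, uniform, starting at 0, excluding `T`.
#' @param values Flow samples in mL/s.
#' @param period Cycle duration T in seconds.
#' @return A `flow_waveform` tibble with attribute `period`.
#' @export
flow_waveform <- function(times, values, period) {
  if (period <= 0) abort("`period` must be positive.")
  if (length(times) != length(values) || length(times) < 4) {
    abort("`times` and `values` must have equal length >= 4.")
  }
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-9 * period) abort("`times` must be uniformly spaced.")
  if (abs(times[1]) > 1e-12 || tail(times, 1) >= period) {
    abort("`times` must start at 0 and end strictly before `period`.")
  }
  out <- tibble(t_s = times, q_mL_s = values)
  structure(out, period = period, class = c("flow_waveform", class(out)))
}

wf_period <- function(q) attr(q, "period")
wf_dt <- function(q) wf_period(q) / nrow(q)

#' @rdname flow_waveform
#' @param stroke_volume_mL Volume ejected per cycle (mL); the waveform integral.
#' @param systole_frac Fraction of the cycle occupied by the systolic half-sine.
#' @param dip_frac Amplitude of the early-diastolic reversal relative to the
#'   systolic peak (0 disables the dip).
#' @param dip_duration_frac Duration of the reversal as a fraction of the cycle.
#' @param n_samples Number of uniform samples over one period.
#' @export
make_waveform <- function(period = 0.85, stroke_volume_mL = 70,
                          systole_frac = 0.35, dip_frac = 0.05,
                          dip_duration_frac = 0.10, n_samples = 256) {
  if (period <= 0 || stroke_volume_mL <= 0) {
    abort("`period` and `stroke_volume_mL` must be positive.")
  }
  if (systole_frac <= 0 || systole_frac >= 1) abort("`systole_frac` must be in (0, 1).")
  if (dip_frac < 0) abort("`dip_frac` must be >= 0.")
  times <- seq(0, period, length.out = n_samples + 1)[seq_len(n_samples)]
  ts <- systole_frac * period
  td <- dip_duration_frac * period
  shape <- numeric(n_samples)
  sys_idx <- times < ts
  shape[sys_idx] <- sin(pi * times[sys_idx] / ts)
  dip_idx <- times >= ts & times < ts + td
  shape[dip_idx] <- -dip_frac * sin(pi * (times[dip_idx] - ts) / td)
  # periodic trapezoid = dt * sum; scale so the integral is the stroke volume
  integral <- (period / n_samples) * sum(shape)
  if (integral <= 0) abort("Waveform shape has non-positive net flow; reduce `dip_frac`.")
  flow_waveform(times, shape * stroke_volume_mL / integral, period)
}

#' Periodic trapezoidal integral of a waveform (mL)
#'
#' With uniform sampling over a full period the trapezoidal rule with periodic
#' closure reduces to `dt * sum(values)`.
#'
#' @param q A [flow_waveform()].
#' @return Integral over one period, in mL.
#' @export
waveform_integral <- function(q) wf_dt(q) * sum(q$q_mL_s)

#' @method glance flow_waveform
#' @export
glance.flow_waveform <- function(x, ...) {
  tibble(period_s = wf_period(x), n_samples = nrow(x),
         stroke_volume_mL = waveform_integral(x),
         mean_mL_s = mean(x$q_mL_s), peak_mL_s = max(x$q_mL_s))
}

# periodic linear interpolation of waveform flow (SI, m^3/s) at times tt
wf_interp_si <- function(q, tt) {
  T <- wf_period(q)
  tm <- tt %% T
  xs <- c(q$t_s, T)
  ys <- c(q$q_mL_s, q$q_mL_s[1])
  mL_s_to_m3_s(approx(xs, ys, xout = tm)$y)
}

# dQ/dt (SI) at times tt: centered periodic differences at the waveform
# samples, then linear interpolation
wf_deriv_si <- function(q, tt) {
  T <- wf_period(q)
  n <- nrow(q)
  dt <- T / n
  v <- q$q_mL_s
  dv <- (v[c(2:n, 1)] - v[c(n, 1:(n - 1))]) / (2 * dt)
  tm <- tt %% T
  xs <- c(q$t_s, T)
  ys <- c(dv, dv[1])
  mL_s_to_m3_s(approx(xs, ys, xout = tm)$y)
}

#' Read/write waveform CSV (`t_s,Q_mL_s`)
#'
#' @param q A [flow_waveform()].
#' @param path CSV file path.
#' @param period Cycle duration; defaults to one sample spacing past the last time.
#' @return `read_waveform_csv()` a `flow_waveform`; `write_waveform_csv()` the
#'   path, invisibly.
#' @export
write_waveform_csv <- function(q, path) {
  utils::write.csv(data.frame(t_s = q$t_s, Q_mL_s = q$q_mL_s), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path, period = NULL) {
  d <- read.csv(path)
  if (!all(c("t_s", "Q_mL_s") %in% names(d))) abort("Expected columns t_s,Q_mL_s.")
  if (is.null(period)) period <- tail(d$t_s, 1) + diff(d$t_s)[1]
  flow_waveform(d$t_s, d$Q_mL_s, period)
}
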