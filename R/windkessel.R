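#' Three-element Windkessel (RCR) terminal loads
#'
#' An RCR load lumps the vasculature downstream of an outlet into a proximal
#' resistance `Rp`, a distal resistance `Rd` (both kg m^-4 s^-1) and a
#' compliance `C` (kg^-1 m^4 s^2). The outlet pressure `P(t)` obeys
#' `P + Rd*C*dP/dt = (Rp + Rd)*Q + Rp*Rd*C*dQ/dt` for a prescribed flow
#' `Q(t)`.
#'
#' @param Rp,Rd Resistances (kg m^-4 s^-1), strictly positive.
#' @param C Compliance (kg^-1 m^4 s^2), strictly positive.
#' @return A one-row `rcr_params` tibble.
#' @export
rcr_params <- function(Rp, Rd, C) {
  if (any(c(Rp, Rd, C) <= 0)) abort("Rp, Rd and C must all be strictly positive.")
  out <- tibble(Rp = Rp, Rd = Rd, C = C)
  class(out) <- c("rcr_params", class(out))
  out
}

#' Systolic/diastolic pressure targets
#'
#' @param systolic,diastolic Target pressures.
#' @param units `"mmHg"` (default, converted at 133.322 Pa/mmHg) or `"Pa"`.
#' @return List with elements `p_sys_Pa`, `p_dia_Pa`.
#' @export
pressure_targets <- function(systolic, diastolic, units = c("mmHg", "Pa")) {
  units <- match.arg(units)
  if (units == "mmHg") {
    systolic <- mmHg_to_Pa(systolic)
    diastolic <- mmHg_to_Pa(diastolic)
  }
  if (!(systolic >= diastolic) || diastolic <= 0) {
    abort("Require systolic >= diastolic > 0.")
  }
  structure(list(p_sys_Pa = systolic, p_dia_Pa = diastolic),
            class = "pressure_targets")
}

pt_check <- function(targets) {
  if (!inherits(targets, "pressure_targets")) {
    abort("`targets` must be created with pressure_targets().")
  }
  targets
}

new_pressure_trace <- function(t_s, p_Pa, params = NULL, converged = NA,
                               cycles = NA_integer_, residual = NA_real_) {
  out <- tibble(t_s = t_s, p_Pa = p_Pa)
  structure(out, params = params, converged = converged, cycles = cycles,
            residual = residual,
            class = c("pressure_trace", class(out)))
}

#' @method glance pressure_trace
#' @export
glance.pressure_trace <- function(x, ...) {
  tibble(p_systolic_Pa = max(x$p_Pa), p_diastolic_Pa = min(x$p_Pa),
         p_systolic_mmHg = Pa_to_mmHg(max(x$p_Pa)),
         p_diastolic_mmHg = Pa_to_mmHg(min(x$p_Pa)),
         converged = attr(x, "converged"), cycles = attr(x, "cycles"),
         residual = attr(x, "residual"))
}

#' Integrate the RCR Windkessel equation for a periodic inflow
#'
#' Advances `P + Rd*C*dP/dt = (Rp+Rd)*Q + Rp*Rd*C*dQ/dt` cycle by cycle with
#' an A-stable one-step scheme (see `method`). `dQ/dt` is evaluated by
#' centered periodic differences at the waveform samples. Cycles are repeated
#' until the
#' maximum cycle-to-cycle pressure change falls below `converge_tol` (relative
#' to the cycle's peak pressure); the last cycle is returned.
#'
#' @param params An [rcr_params()] row.
#' @param q A [flow_waveform()].
#' @param p0 Initial pressure (Pa); defaults to the steady value
#'   `(Rp+Rd) * mean(Q)`.
#' @param dt Time step (s); must satisfy `dt <= T/50`.
#' @param min_cycles,max_cycles Cycle bounds.
#' @param converge_tol Relative periodic steady-state criterion (default
#'   0.06%).
#' @param method One-step scheme: `"exponential"` (default; integrating
#'   factor, exact when the forcing is linear within a step), implicit
#'   `"trapezoidal"` (Crank-Nicolson), or first-order `"backward_euler"`.
#' @param require_convergence Abort (with the residual) if the criterion is
#'   not met within `max_cycles`.
#' @return A `pressure_trace` tibble (`t_s`, `p_Pa`) over the last cycle, with
#'   `converged`, `cycles`, `residual` attributes.
#' @export
solve_rcr <- function(params, q, p0 = NULL, dt = 0.004,
                      min_cycles = 3, max_cycles = 50, converge_tol = 6e-4,
                      method = c("exponential", "trapezoidal", "backward_euler"),
                      require_convergence = TRUE) {
  method <- match.arg(method)
  T <- wf_period(q)
  if (dt > T / 50 + 1e-12) abort("`dt` must be at most T/50.")
  # align solver nodes with the waveform samples so the piecewise-linear
  # forcing has no kinks inside a step (the requested dt is an upper bound)
  n0 <- max(50L, round(T / dt))
  n_wf <- nrow(q)
  n <- as.integer(n_wf * ceiling(n0 / n_wf))
  dt <- T / n
  tt <- (0:n) * dt  # one cycle including the wrap point
  Q <- wf_interp_si(q, tt)
  dQ <- wf_deriv_si(q, tt)
  Rp <- params$Rp[1]; Rd <- params$Rd[1]; C <- params$C[1]
  tau <- Rd * C
  S <- (Rp + Rd) * Q + Rp * tau * dQ  # forcing (Pa)

  P <- p0 %||% ((Rp + Rd) * mean(Q[-(n + 1)]))
  prev_cycle <- NULL
  residual <- Inf
  cycles <- 0L
  trace <- numeric(n + 1)
  a <- dt / tau
  E <- exp(-a)
  dS <- (S[-1] - S[-(n + 1)]) / a  # slope term tau*dS/dt per step
  while (cycles < max_cycles) {
    trace[1] <- P
    if (method == "exponential") {
      for (k in seq_len(n)) {
        trace[k + 1] <- S[k + 1] - dS[k] + (trace[k] - S[k] + dS[k]) * E
      }
    } else if (method == "trapezoidal") {
      for (k in seq_len(n)) {
        trace[k + 1] <- (trace[k] * (1 - a / 2) + (a / 2) * (S[k] + S[k + 1])) / (1 + a / 2)
      }
    } else {
      for (k in seq_len(n)) {
        trace[k + 1] <- (trace[k] + a * S[k + 1]) / (1 + a)
      }
    }
    P <- trace[n + 1]
    cycles <- cycles + 1L
    if (!is.null(prev_cycle)) {
      residual <- max(abs(trace - prev_cycle)) / max(abs(trace))
      if (cycles >= min_cycles && residual < converge_tol) break
    }
    prev_cycle <- trace
  }
  converged <- is.finite(residual) && residual < converge_tol
  if (require_convergence && !converged) {
    abort(sprintf(
      "RCR integration did not reach periodic steady state in %d cycles (residual %.3g).",
      max_cycles, residual))
  }
  new_pressure_trace(tt[seq_len(n)], trace[seq_len(n)], params = params,
                     converged = converged, cycles = cycles, residual = residual)
}

#' Calibrate RCR parameters to systolic/diastolic pressure targets
#'
#' Iteratively adjusts the total resistance `Rtot = Rp + Rd` and the
#' compliance `C` until the simulated last-cycle pressure extrema match the
#' targets. The proximal/distal split `gamma = Rp/(Rp+Rd)` is held fixed
#' during calibration. `Rtot` is initialised from the mean-pressure proxy
#' `(p_sys + 2*p_dia)/3` over the mean flow and updated multiplicatively from
#' the same proxy; `C` follows a damped multiplicative update on the pulse
#' pressure. Infeasible pulse-pressure demands (outside the range achievable
#' for any compliance at the given `gamma`) abort with the achievable bounds.
#'
#' For a pulseless waveform with equal targets the resistance is returned
#' directly and the compliance is unidentifiable: it is set to `C0` and
#' flagged via the `unidentifiable_C` attribute.
#'
#' @param q A [flow_waveform()] with positive mean flow.
#' @param targets A [pressure_targets()].
#' @param gamma Fixed ratio `Rp/(Rp+Rd)` in (0, 1).
#' @param tol Relative tolerance on both pressure extrema.
#' @param C0 Initial compliance; default scales the cycle period by the
#'   initial distal resistance.
#' @param max_iter Iteration cap.
#' @param dt,converge_tol Passed to [solve_rcr()].
#' @return An [rcr_params()] row with attributes `iterations`, `achieved`
#'   (tibble of simulated extrema) and `unidentifiable_C`.
#' @export
calibrate_rcr <- function(q, targets, gamma = 0.09, tol = 1e-3, C0 = NULL,
                          max_iter = 60, dt = 0.004, converge_tol = 6e-4) {
  pt_check(targets)
  if (gamma <= 0 || gamma >= 1) abort("`gamma` must lie strictly between 0 and 1.")
  q_si <- mL_s_to_m3_s(q$q_mL_s)
  q_mean <- mean(q_si)
  if (q_mean <= 0) abort("Calibration requires positive mean inlet flow.")
  p_sys_t <- targets$p_sys_Pa; p_dia_t <- targets$p_dia_Pa
  p_mean_t <- (p_sys_t + 2 * p_dia_t) / 3
  pp_t <- p_sys_t - p_dia_t
  rtot <- p_mean_t / q_mean
  q_range <- max(q_si) - min(q_si)

  # degenerate: pulseless waveform
  if (q_range < 1e-9 * max(abs(q_si))) {
    if (pp_t > tol * p_sys_t) {
      abort("Pulse-pressure target cannot be met with a pulseless waveform.")
    }
    rtot <- p_sys_t / q_mean
    C <- C0 %||% (wf_period(q) / ((1 - gamma) * rtot))
    out <- rcr_params(gamma * rtot, (1 - gamma) * rtot, C)
    attr(out, "unidentifiable_C") <- TRUE
    attr(out, "iterations") <- 0L
    inform("Compliance is unidentifiable for a pulseless waveform; returning C0.")
    return(out)
  }

  # achievable pulse-pressure range at this gamma (C -> Inf and C -> 0 limits)
  sim_pp <- function(C, rt) {
    tr <- solve_rcr(rcr_params(gamma * rt, (1 - gamma) * rt, C), q, dt = dt,
                    converge_tol = converge_tol, require_convergence = FALSE,
                    max_cycles = 30)
    c(max(tr$p_Pa), min(tr$p_Pa))
  }
  lim_lo <- sim_pp(1e-6, rtot)   # near-infinite compliance
  lim_hi <- sim_pp(1e-12, rtot)  # near-zero compliance
  pp_lo <- lim_lo[1] - lim_lo[2]
  pp_hi <- lim_hi[1] - lim_hi[2]
  if (pp_t < 0.95 * pp_lo || pp_t > 1.05 * pp_hi) {
    abort(sprintf(
      paste0("Pulse-pressure target %.1f mmHg is outside the achievable range ",
             "[%.1f, %.1f] mmHg for gamma = %.3f with this waveform."),
      Pa_to_mmHg(pp_t), Pa_to_mmHg(pp_lo), Pa_to_mmHg(pp_hi), gamma))
  }

  C <- C0 %||% (1.5 * wf_period(q) / ((1 - gamma) * rtot))
  achieved <- NULL
  for (it in seq_len(max_iter)) {
    tr <- solve_rcr(rcr_params(gamma * rtot, (1 - gamma) * rtot, C), q, dt = dt,
                    converge_tol = converge_tol, require_convergence = FALSE,
                    max_cycles = 30)
    p_sys <- max(tr$p_Pa); p_dia <- min(tr$p_Pa)
    achieved <- tibble(p_sys_Pa = p_sys, p_dia_Pa = p_dia)
    if (abs(p_sys - p_sys_t) <= tol * p_sys_t &&
        abs(p_dia - p_dia_t) <= tol * p_dia_t) {
      out <- rcr_params(gamma * rtot, (1 - gamma) * rtot, C)
      attr(out, "iterations") <- it
      attr(out, "achieved") <- achieved
      attr(out, "unidentifiable_C") <- FALSE
      return(out)
    }
    rtot <- rtot * p_mean_t / ((p_sys + 2 * p_dia) / 3)
    pp <- max(p_sys - p_dia, 1e-12)
    C <- min(max(C * (pp / pp_t)^0.7, 1e-12), 1e-6)
  }
  abort(sprintf(
    "Calibration did not converge in %d iterations (achieved %.1f/%.1f mmHg vs target %.1f/%.1f).",
    max_iter, Pa_to_mmHg(achieved$p_sys_Pa), Pa_to_mmHg(achieved$p_dia_Pa),
    Pa_to_mmHg(p_sys_t), Pa_to_mmHg(p_dia_t)))
}

#' Distribute a global RCR load over outlets by area ratio
#'
#' Splits a calibrated global Windkessel over the outlets proportionally to
#' their areas: `Rp_i = Rp * Atot/Ai`, `Rd_i = Rd * Atot/Ai`,
#' `C_i = C * Ai/Atot`. The parallel combination of the distributed loads
#' recovers the global parameters exactly, and the distal time constant
#' `Rd_i * C_i` is outlet-independent.
#'
#' @param global_params An [rcr_params()] row.
#' @param outlets Tibble with columns `outlet` and `area` (any consistent
#'   unit; only area ratios enter), e.g. from [outlet_areas()] (use the
#'   `area_m2` or `area_cm2` column as `area`).
#' @return Tibble with columns `outlet`, `Rp`, `Rd`, `C`.
#' @export
distribute_rcr <- function(global_params, outlets) {
  outlets <- as_tibble(outlets)
  if (!all(c("outlet", "area") %in% names(outlets))) {
    if (all(c("outlet", "area_m2") %in% names(outlets))) {
      outlets <- dplyr::rename(outlets, area = "area_m2")
    } else {
      abort("`outlets` needs columns `outlet` and `area`.")
    }
  }
  if (nrow(outlets) < 1) abort("At least one outlet is required.")
  if (any(outlets$area <= 0)) abort("Outlet areas must be strictly positive.")
  if (anyDuplicated(outlets$outlet)) abort("Outlet labels must be unique.")
  atot <- sum(outlets$area)
  tibble(outlet = outlets$outlet,
         Rp = global_params$Rp[1] * atot / outlets$area,
         Rd = global_params$Rd[1] * atot / outlets$area,
         C = global_params$C[1] * outlets$area / atot)
}

#' Packaged reference RCR parameter sets (three patient cases)
#'
#' Per-outlet distal resistance, proximal resistance and compliance for the
#' four outlets (BCA, LCCA, LSA, DA) of three treated patient cases, in
#' kg m^-4 s^-1 and kg^-1 m^4 s^2.
#'
#' @return Tibble with columns `case`, `outlet`, `Rd`, `Rp`, `C`.
#' @export
rcr_reference_cases <- function() {
  path <- system.file("extdata", "rcr_reference_cases.csv", package = "pauhemo")
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Check internal consistency of a per-outlet RCR table
#'
#' An area-ratio distribution implies, within each case, that (a) `Rd_i/Rp_i`
#' is constant across outlets, (b) the distal time constant `Rd_i*C_i` is
#' constant, and (c) the outlet area fractions implied independently by
#' `1/Rp`, `1/Rd` and `C` agree. Reported spreads are relative
#' (`(max - min)/mean`); outlets whose `Rd/Rp` or `Rd*C` deviates from the
#' case median by more than `flag_tol` are flagged with the violated relation.
#'
#' @param table Tibble with columns `case` (optional, single case assumed if
#'   absent), `outlet`, `Rd`, `Rp`, `C`.
#' @param flag_tol Relative deviation that flags an outlet.
#' @return Tibble with one row per case: `spread_ratio`, `spread_tau`,
#'   `spread_area`, and a `flags` list-column of per-outlet violations.
#' @export
validate_rcr_table <- function(table, flag_tol = 0.05) {
  table <- as_tibble(table)
  if (!"case" %in% names(table)) table$case <- "case"
  need <- c("outlet", "Rd", "Rp", "C")
  if (!all(need %in% names(table))) {
    abort(paste("`table` needs columns:", paste(need, collapse = ", ")))
  }
  rel_spread <- function(x) (max(x) - min(x)) / mean(x)
  per_case <- function(d) {
    ratio <- d$Rd / d$Rp
    tau <- d$Rd * d$C
    fr <- function(w) w / sum(w)
    af <- cbind(fr(1 / d$Rp), fr(1 / d$Rd), fr(d$C))
    spread_area <- max(apply(af, 1, rel_spread))
    flags <- tibble(outlet = character(0), relation = character(0),
                    deviation = numeric(0))
    dev_ratio <- abs(ratio / stats::median(ratio) - 1)
    dev_tau <- abs(tau / stats::median(tau) - 1)
    if (any(dev_ratio > flag_tol)) {
      i <- which(dev_ratio > flag_tol)
      flags <- bind_rows(flags, tibble(outlet = d$outlet[i],
                                       relation = "Rd/Rp", deviation = dev_ratio[i]))
    }
    if (any(dev_tau > flag_tol)) {
      i <- which(dev_tau > flag_tol)
      flags <- bind_rows(flags, tibble(outlet = d$outlet[i],
                                       relation = "Rd*C", deviation = dev_tau[i]))
    }
    tibble(spread_ratio = rel_spread(ratio), spread_tau = rel_spread(tau),
           spread_area = spread_area, n_outlets = nrow(d), flags = list(flags))
  }
  table |>
    group_by(.data$case) |>
    dplyr::group_modify(~ per_case(.x)) |>
    ungroup()
}

#' @importFrom rlang .data
NULL
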