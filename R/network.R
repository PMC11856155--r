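#' Lumped-parameter (0D) vascular network
#'
#' A `vessel_network` is a resistive segment graph driven by a prescribed
#' inflow at the single inlet node, with each outlet terminated by a
#' three-element Windkessel load referenced to zero venous pressure. Segment
#' resistances follow Poiseuille's law; junction pressures are single-valued.
#'
#' @param segments Tibble with columns `from`, `to`, `label`, `length_m`,
#'   `diameter_m` (and optionally a precomputed `R`).
#' @param terminals Tibble with columns `outlet` (node name without the `t_`
#'   prefix convention enforced; terminal node = `t_<outlet>`), `Rp`, `Rd`,
#'   `C`.
#' @param inlet Inlet node name.
#' @param viscosity Dynamic viscosity (Pa s), default 3.5e-3.
#' @param density Fluid density (kg/m^3), default 1060 (carried as metadata).
#' @return A `vessel_network` object.
#' @export
vessel_network <- function(segments, terminals, inlet = "inlet",
                           viscosity = 3.5e-3, density = 1060) {
  segments <- as_tibble(segments)
  terminals <- as_tibble(terminals)
  if (!all(c("from", "to", "label") %in% names(segments))) {
    abort("`segments` needs columns from, to, label.")
  }
  if (!"R" %in% names(segments)) {
    if (!all(c("length_m", "diameter_m") %in% names(segments))) {
      abort("`segments` needs length_m and diameter_m (or a precomputed R).")
    }
    segments$R <- poiseuille_resistance(segments$length_m, segments$diameter_m,
                                        viscosity)
  }
  if (any(segments$R <= 0)) abort("Segment resistances must be positive.")
  if (!all(c("outlet", "Rp", "Rd", "C") %in% names(terminals))) {
    abort("`terminals` needs columns outlet, Rp, Rd, C.")
  }
  nodes <- unique(c(inlet, segments$from, segments$to))
  tnodes <- paste0("t_", terminals$outlet)
  if (!all(tnodes %in% nodes)) {
    abort(paste("Terminal node(s) missing from segments:",
                paste(setdiff(tnodes, nodes), collapse = ", ")))
  }
  # connectivity: every terminal reachable from the inlet
  reach <- inlet
  repeat {
    nxt <- unique(c(segments$to[segments$from %in% reach],
                    segments$from[segments$to %in% reach]))
    new <- setdiff(nxt, reach)
    if (length(new) == 0) break
    reach <- c(reach, new)
  }
  if (!all(tnodes %in% reach)) {
    abort(paste("Outlet terminal(s) not connected to the inlet:",
                paste(setdiff(tnodes, reach), collapse = ", ")))
  }
  structure(list(segments = segments, terminals = terminals, inlet = inlet,
                 nodes = nodes, viscosity = viscosity, density = density),
            class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("<vessel_network: %d nodes, %d segments, %d RCR terminals>\n",
              length(x$nodes), nrow(x$segments), nrow(x$terminals)))
  invisible(x)
}

#' Poiseuille resistance of a cylindrical segment
#'
#' `R = 128 * mu * L / (pi * D^4)` in kg m^-4 s^-1.
#'
#' @param length_m Segment length (m).
#' @param diameter_m Effective lumen diameter (m).
#' @param viscosity Dynamic viscosity (Pa s).
#' @return Resistance (kg m^-4 s^-1).
#' @export
poiseuille_resistance <- function(length_m, diameter_m, viscosity = 3.5e-3) {
  if (any(diameter_m <= 0)) abort("Diameters must be positive.")
  128 * viscosity * length_m / (pi * diameter_m^4)
}

#' Build a 0D network from a generated vessel and branch morphometry
#'
#' Converts the vessel's segment skeleton (exact parametric lengths and
#' diameters, including the treatment-specific LSA-origin narrowing, origin
#' coverage and bypass conduit) into a resistive network. Branch segment
#' diameters are overridden by measured morphometry where supplied: the
#' effective diameter of a summarised branch is `2*sqrt(avg_area/pi)`.
#'
#' @param vessel A `synthetic_vessel`.
#' @param terminals Per-outlet RCR loads (tibble `outlet`, `Rp`, `Rd`, `C`),
#'   e.g. from [distribute_rcr()].
#' @param morpho Named list of `morpho_summary` rows per branch label
#'   ([truth_morpho()] provides the generator ground truth). Every branch of
#'   the vessel must be covered; a missing branch aborts with its name.
#' @param viscosity,density Blood properties (Pa s, kg/m^3).
#' @return A [vessel_network()].
#' @export
network_from_geometry <- function(vessel, terminals, morpho = truth_morpho(vessel),
                                  viscosity = 3.5e-3, density = 1060) {
  sk <- vessel$skeleton
  labels <- vessel$spec$branches$label
  missing <- setdiff(labels, names(morpho))
  if (length(missing) > 0) {
    abort(paste("Missing morphometry for branch:", paste(missing, collapse = ", ")))
  }
  dia <- sk$diameter_mm
  for (lbl in labels) {
    d_eff <- 2 * sqrt(morpho[[lbl]]$avg_area_cm2 / pi) * 10  # cm^2 -> mm
    hit <- sk$label == lbl | sk$label == paste0(lbl, "_origin") |
      sk$label == paste0(lbl, "_distal")
    # scale the skeleton diameters by the measured/nominal ratio so the
    # narrowed-origin profile is preserved
    d_nom <- vessel$spec$branches$diameter_mm[labels == lbl]
    dia[hit] <- sk$diameter_mm[hit] * d_eff / d_nom
  }
  segments <- tibble(from = sk$from, to = sk$to, label = sk$label,
                     length_m = mm_to_m(sk$length_mm),
                     diameter_m = mm_to_m(dia))
  vessel_network(segments, terminals, inlet = "inlet",
                 viscosity = viscosity, density = density)
}

#' Solve a 0D network for a periodic inflow
#'
#' Per time step, solves the nodal system (Kirchhoff current law over the
#' resistive segments, with each terminal's Windkessel state advanced by an
#' implicit Euler step) and iterates cardiac cycles until the maximum
#' cycle-to-cycle change of any node pressure falls below `converge_tol`.
#'
#' @param net A [vessel_network()].
#' @param inflow A [flow_waveform()] prescribed at the inlet node.
#' @param dt Time step (s), at most `T/50`.
#' @param min_cycles,max_cycles Cycle bounds.
#' @param converge_tol Relative periodic steady-state criterion (default
#'   0.06%).
#' @return A `network_solution`: list with tibbles `pressures` (`node`,
#'   `t_s`, `p_Pa`), `flows` (`label`, `from`, `to`, `t_s`, `q_m3_s`),
#'   `outlet_summary` (`outlet`, `mean_flow_m3_s`, `share_pct`), and
#'   attributes `converged`, `cycles`, `residual`,
#'   `max_conservation_residual`.
#' @export
solve_network <- function(net, inflow, dt = 0.004, min_cycles = 3,
                          max_cycles = 60, converge_tol = 6e-4) {
  T <- wf_period(inflow)
  if (dt > T / 50 + 1e-12) abort("`dt` must be at most T/50.")
  n <- max(50L, round(T / dt))
  dt <- T / n
  tt <- (0:n) * dt
  Qin <- wf_interp_si(inflow, tt)

  nodes <- net$nodes
  ni <- seq_along(nodes)
  names(ni) <- nodes
  seg <- net$segments
  i_from <- ni[seg$from]; i_to <- ni[seg$to]
  G <- matrix(0, length(nodes), length(nodes))
  for (k in seq_len(nrow(seg))) {
    g <- 1 / seg$R[k]
    a <- i_from[k]; b <- i_to[k]
    G[a, a] <- G[a, a] + g; G[b, b] <- G[b, b] + g
    G[a, b] <- G[a, b] - g; G[b, a] <- G[b, a] - g
  }
  term <- net$terminals
  i_term <- ni[paste0("t_", term$outlet)]
  # implicit-Euler terminal elimination:
  # Pc' = (Pc + (dt/(C*Rp)) P) / beta,  Q = (P - Pc') / Rp = aP - b(Pc)
  beta <- 1 + (dt / term$C) * (1 / term$Rp + 1 / term$Rd)
  a_t <- (1 - (dt / (term$C * term$Rp)) / beta) / term$Rp
  A <- G
  for (j in seq_along(i_term)) A[i_term[j], i_term[j]] <- A[i_term[j], i_term[j]] + a_t[j]
  Ainv <- tryCatch(solve(A), error = function(e) {
    abort("Singular nodal matrix: check that every node connects to a terminal.")
  })

  Pc <- rep(0, nrow(term))  # terminal compliance-node pressures
  P_hist <- matrix(0, length(nodes), n)
  prev_hist <- NULL
  residual <- Inf
  cycles <- 0L
  while (cycles < max_cycles) {
    for (k in seq_len(n)) {
      rhs <- numeric(length(nodes))
      rhs[ni[net$inlet]] <- Qin[k]
      rhs[i_term] <- rhs[i_term] + (Pc / beta) / term$Rp
      P <- Ainv %*% rhs
      P_hist[, k] <- P
      Pc <- (Pc + (dt / (term$C * term$Rp)) * P[i_term]) / beta
    }
    cycles <- cycles + 1L
    if (!is.null(prev_hist)) {
      residual <- max(abs(P_hist - prev_hist)) / max(abs(P_hist))
      if (cycles >= min_cycles && residual < converge_tol) break
    }
    prev_hist <- P_hist + 0  # copy
  }

  t_cycle <- tt[seq_len(n)]
  pressures <- tibble(
    node = rep(nodes, each = n),
    t_s = rep(t_cycle, times = length(nodes)),
    p_Pa = as.vector(t(P_hist))
  )
  qmat <- (P_hist[i_from, , drop = FALSE] - P_hist[i_to, , drop = FALSE]) / seg$R
  flows <- tibble(
    label = rep(seg$label, each = n),
    from = rep(seg$from, each = n),
    to = rep(seg$to, each = n),
    t_s = rep(t_cycle, times = nrow(seg)),
    q_m3_s = as.vector(t(qmat))
  )
  # outlet flows: the segment into each terminal node
  mean_in <- mean(Qin[seq_len(n)])
  outlet_summary <- purrr::map_dfr(seq_len(nrow(term)), function(j) {
    tn <- paste0("t_", term$outlet[j])
    qs <- flows |> filter(.data$to == tn) |> group_by(.data$t_s) |>
      summarise(q = sum(.data$q_m3_s), .groups = "drop")
    tibble(outlet = term$outlet[j],
           mean_flow_m3_s = mean(qs$q),
           share_pct = 100 * mean(qs$q) / mean_in)
  })
  # conservation residual at internal nodes (inlet carries the source)
  internal <- setdiff(nodes, c(net$inlet, paste0("t_", term$outlet)))
  max_resid <- 0
  if (length(internal) > 0) {
    for (nd in internal) {
      i <- ni[nd]
      net_in <- colSums(qmat[i_to == i, , drop = FALSE]) -
        colSums(qmat[i_from == i, , drop = FALSE])
      max_resid <- max(max_resid, max(abs(net_in)) / max(abs(Qin)))
    }
  }
  structure(list(pressures = pressures, flows = flows,
                 outlet_summary = outlet_summary, dt = dt, period = T),
            converged = is.finite(residual) && residual < converge_tol,
            cycles = cycles, residual = residual,
            max_conservation_residual = max_resid,
            class = "network_solution")
}

#' @export
print.network_solution <- function(x, ...) {
  cat(sprintf("<network_solution: %d cycles, residual %.2g>\n",
              attr(x, "cycles"), attr(x, "residual")))
  print(x$outlet_summary)
  invisible(x)
}

#' @method tidy network_solution
#' @export
tidy.network_solution <- function(x, ...) x$flows

#' @method glance network_solution
#' @export
glance.network_solution <- function(x, ...) {
  tibble(cycles = attr(x, "cycles"), residual = attr(x, "residual"),
         converged = attr(x, "converged"),
         max_conservation_residual = attr(x, "max_conservation_residual"))
}

#' Node pressure at a given time
#'
#' @param solution A `network_solution`.
#' @param node Node name.
#' @param t Time (s) within the cycle; nearest sample is used.
#' @return Pressure in Pa.
#' @export
node_pressure_at <- function(solution, node, t) {
  d <- solution$pressures |> filter(.data$node == !!node)
  if (nrow(d) == 0) abort(sprintf("Unknown node '%s'.", node))
  d$p_Pa[which.min(abs(d$t_s - t))]
}
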