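#' Compare treatment configurations in the 0D network model
#'
#' Runs the lumped network for each supplied configuration under identical
#' terminal loads (calibrated once and distributed by the baseline outlet
#' areas) and identical inflow, so differences stem from geometry alone.
#' Reports, per configuration, the LSA mean-flow share of inlet flow, its
#' decrement relative to the baseline (`PRE`), and the pressure drop between
#' the LSA take-off junction on the arch and the LSA outlet node at the
#' systolic peak (the instant of maximum inlet flow), in mmHg.
#'
#' @param specs Named list of [aorta_spec()]s (must include `"PRE"`); all
#'   specs must share the branch layout (labels, positions, diameters,
#'   angles).
#' @param inflow A [flow_waveform()].
#' @param targets A [pressure_targets()] for terminal calibration.
#' @param gamma Proximal resistance fraction during calibration.
#' @param vessels Optional named list of prebuilt `synthetic_vessel`s
#'   (skips meshing; they are otherwise generated with [make_aorta()]).
#' @param morpho Optional named list (per configuration) of per-branch
#'   `morpho_summary` lists; defaults to generator ground truth.
#' @param dt,converge_tol Network solver settings.
#' @return A `config_comparison` tibble: `configuration`, `lsa_share_pct`,
#'   `decrement_pct`, `dp_arch_lsa_mmHg`, with the solutions attached as the
#'   `solutions` attribute.
#' @export
compare_configurations <- function(specs, inflow, targets, gamma = 0.09,
                                   vessels = NULL, morpho = NULL,
                                   dt = 0.004, converge_tol = 6e-4) {
  if (!"PRE" %in% names(specs)) abort("`specs` must include a PRE baseline.")
  layout <- lapply(specs, function(s) {
    s$branches[, c("label", "position_deg", "diameter_mm", "angle_deg", "length_mm")]
  })
  for (nm in names(layout)) {
    if (!isTRUE(all.equal(layout[[nm]], layout[["PRE"]], check.attributes = FALSE))) {
      abort(sprintf("Configuration '%s' does not share the PRE branch layout.", nm))
    }
  }
  vessels <- vessels %||% lapply(specs, make_aorta)

  global <- calibrate_rcr(inflow, targets, gamma = gamma, dt = dt,
                          converge_tol = converge_tol)
  areas <- outlet_areas(vessels[["PRE"]]) |> rename(area = "area_m2")
  terminals <- distribute_rcr(global, areas[, c("outlet", "area")])

  t_peak <- inflow$t_s[which.max(inflow$q_mL_s)]
  rows <- list()
  sols <- list()
  for (nm in names(specs)) {
    mo <- if (!is.null(morpho) && !is.null(morpho[[nm]])) morpho[[nm]] else
      truth_morpho(vessels[[nm]])
    net <- network_from_geometry(vessels[[nm]], terminals, morpho = mo)
    sol <- solve_network(net, inflow, dt = dt, converge_tol = converge_tol)
    share <- sol$outlet_summary$share_pct[sol$outlet_summary$outlet == "LSA"]
    dp <- node_pressure_at(sol, "j_LSA", t_peak) - node_pressure_at(sol, "t_LSA", t_peak)
    rows[[nm]] <- tibble(configuration = nm, lsa_share_pct = share,
                         dp_arch_lsa_mmHg = Pa_to_mmHg(dp))
    sols[[nm]] <- sol
  }
  out <- bind_rows(rows)
  pre_share <- out$lsa_share_pct[out$configuration == "PRE"]
  out <- out |>
    mutate(decrement_pct = 100 * (pre_share - .data$lsa_share_pct) / pre_share) |>
    select("configuration", "lsa_share_pct", "decrement_pct", "dp_arch_lsa_mmHg")
  structure(out, solutions = sols, terminals = terminals,
            class = c("config_comparison", class(out)))
}

#' Sweep the LSA-origin narrowing at network level
#'
#' Evaluates the LSA mean-flow share and arch-to-LSA pressure drop over a
#' grid of origin narrowing fractions, rebuilding only the network skeleton
#' (the D^-4 resistance law), not the surface mesh. LSA flow is monotone
#' non-increasing and the pressure drop monotone non-decreasing in the
#' narrowing.
#'
#' @param spec_pre A PRE [aorta_spec()] defining the shared anatomy.
#' @param narrowings Vector of narrowing fractions in `[0, 1)`.
#' @param inflow,targets,gamma,dt As in [compare_configurations()].
#' @return Tibble: `lsa_narrowing`, `lsa_share_pct`, `dp_arch_lsa_mmHg`.
#' @export
lsa_narrowing_sweep <- function(spec_pre, narrowings, inflow, targets,
                                gamma = 0.09, dt = 0.004) {
  global <- calibrate_rcr(inflow, targets, gamma = gamma, dt = dt)
  frame <- aorta_frame(spec_pre)
  areas <- tibble(
    outlet = c(names(frame$branches), "DA"),
    area = c(vapply(frame$branches, function(b) pi * mm_to_m(b$radius)^2, numeric(1)),
             pi * mm_to_m(frame$radius_at(frame$main_len))^2))
  terminals <- distribute_rcr(global, areas)
  t_peak <- inflow$t_s[which.max(inflow$q_mL_s)]

  purrr::map_dfr(narrowings, function(w) {
    sp <- spec_pre
    sp$configuration <- if (w > 0) "SBSG" else "PRE"
    sp$lsa_narrowing <- w
    sk <- aorta_skeleton(sp)
    segments <- tibble(from = sk$from, to = sk$to, label = sk$label,
                       length_m = mm_to_m(sk$length_mm),
                       diameter_m = mm_to_m(sk$diameter_mm))
    net <- vessel_network(segments, terminals)
    sol <- solve_network(net, inflow, dt = dt)
    dp <- node_pressure_at(sol, "j_LSA", t_peak) - node_pressure_at(sol, "t_LSA", t_peak)
    tibble(lsa_narrowing = w,
           lsa_share_pct = sol$outlet_summary$share_pct[sol$outlet_summary$outlet == "LSA"],
           dp_arch_lsa_mmHg = Pa_to_mmHg(dp))
  })
}
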