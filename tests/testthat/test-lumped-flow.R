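test_that("Poiseuille resistance evaluates the D^-4 law", {
  expect_equal(poiseuille_resistance(0.1, 0.02, 3.5e-3),
               128 * 3.5e-3 * 0.1 / (pi * 0.02^4), tolerance = 1e-12)
  expect_equal(poiseuille_resistance(0.1, 0.02), 8.913e4, tolerance = 1e-3)
  expect_equal(poiseuille_resistance(0.1, 0.01) / poiseuille_resistance(0.1, 0.02),
               16, tolerance = 1e-12)
})

test_that("a single tube with an RCR load reduces to series resistances", {
  qc <- flow_waveform(tgrid(0.85, 128), rep(100, 128), 0.85)
  segs <- tibble::tibble(from = "inlet", to = "t_DA", label = "tube",
                         length_m = 0.1, diameter_m = 0.02)
  term <- tibble::tibble(outlet = "DA", Rp = 1e7, Rd = 1e8, C = 1e-9)
  sol <- solve_network(vessel_network(segs, term), qc, max_cycles = 100)
  r_tot <- poiseuille_resistance(0.1, 0.02) + 1e7 + 1e8
  p_in <- max(sol$pressures$p_Pa[sol$pressures$node == "inlet"])
  expect_equal(p_in, r_tot * 1e-4, tolerance = 1e-3)
})

test_that("identical parallel branches split the flow evenly", {
  segs <- tibble::tibble(from = c("inlet", "j", "j"),
                         to = c("j", "t_A", "t_B"),
                         label = c("trunk", "a", "b"),
                         length_m = c(0.05, 0.1, 0.1),
                         diameter_m = c(0.02, 0.01, 0.01))
  term <- tibble::tibble(outlet = c("A", "B"), Rp = c(1e7, 1e7),
                         Rd = c(1e8, 1e8), C = c(1e-9, 1e-9))
  sol <- solve_network(vessel_network(segs, term), fx_waveform())
  expect_equal(sol$outlet_summary$share_pct, c(50, 50), tolerance = 1e-3)
  expect_equal(sum(sol$outlet_summary$share_pct), 100, tolerance = 1e-6)
})

test_that("flow is conserved at every junction and time step", {
  v <- fx_vessel("PRE")
  term <- distribute_rcr(rcr_params(1.2e7, 1.3e8, 1.1e-8),
                         dplyr::rename(outlet_areas(v), area = "area_m2"))
  sol <- solve_network(network_from_geometry(v, term), fx_waveform())
  expect_lt(attr(sol, "max_conservation_residual"), 1e-9)
  expect_true(attr(sol, "converged"))
})

test_that("a 4-outlet network matches a monolithic ODE reference", {
  skip_if_not_installed("deSolve")
  v <- fx_vessel("PRE")
  term <- distribute_rcr(rcr_params(1.2e7, 1.3e8, 1.1e-8),
                         dplyr::rename(outlet_areas(v), area = "area_m2"))
  net <- network_from_geometry(v, term)
  q <- fx_waveform()
  sol <- solve_network(net, q, max_cycles = 80)

  # reference: states = terminal compliance pressures; node pressures solve
  # the same linear system, assembled independently here
  nodes <- net$nodes
  ni <- stats::setNames(seq_along(nodes), nodes)
  seg <- net$segments
  G <- matrix(0, length(nodes), length(nodes))
  for (k in seq_len(nrow(seg))) {
    a <- ni[seg$from[k]]; b <- ni[seg$to[k]]; g <- 1 / seg$R[k]
    G[a, a] <- G[a, a] + g; G[b, b] <- G[b, b] + g
    G[a, b] <- G[a, b] - g; G[b, a] <- G[b, a] - g
  }
  term_idx <- ni[paste0("t_", net$terminals$outlet)]
  A0 <- G
  for (j in seq_along(term_idx)) {
    A0[term_idx[j], term_idx[j]] <- A0[term_idx[j], term_idx[j]] +
      1 / net$terminals$Rp[j]
  }
  rhs_fun <- function(t, y, parms) {
    rhs <- numeric(length(nodes))
    rhs[ni[["inlet"]]] <- pauhemo:::wf_interp_si(q, t)
    rhs[term_idx] <- rhs[term_idx] + y / net$terminals$Rp
    P <- solve(A0, rhs)
    Qt <- (P[term_idx] - y) / net$terminals$Rp
    list(as.vector((Qt - y / net$terminals$Rd) / net$terminals$C),
         P = as.vector(P))
  }
  times <- seq(0, 6 * 0.85, by = 0.00425)
  ref <- deSolve::ode(y = rep(0, 4), times = times, func = rhs_fun,
                      rtol = 1e-10, atol = 1e-2)
  # mean outlet flows over the final reference cycle
  last <- ref[times >= 5 * 0.85 - 1e-9, ]
  for (j in seq_along(term_idx)) {
    Pnode <- last[, 1 + 4 + term_idx[j]]
    Pc <- last[, 1 + j]
    q_ref <- mean((Pnode - Pc) / net$terminals$Rp[j])
    q_pkg <- sol$outlet_summary$mean_flow_m3_s[j]
    expect_equal(q_pkg, q_ref, tolerance = 5e-3,
                 label = sprintf("mean flow %s", net$terminals$outlet[j]))
  }
})

test_that("disconnected outlets are rejected by construction", {
  segs <- tibble::tibble(from = "inlet", to = "t_A", label = "a",
                         length_m = 0.1, diameter_m = 0.01)
  term <- tibble::tibble(outlet = c("A", "B"), Rp = c(1e7, 1e7),
                         Rd = c(1e8, 1e8), C = c(1e-9, 1e-9))
  expect_error(vessel_network(segs, term), "missing from segments|not connected")
})

test_that("missing branch morphometry aborts with the branch name", {
  v <- fx_vessel("PRE")
  term <- distribute_rcr(rcr_params(1.2e7, 1.3e8, 1.1e-8),
                         dplyr::rename(outlet_areas(v), area = "area_m2"))
  mo <- truth_morpho(v)
  expect_error(network_from_geometry(v, term, morpho = mo[c("BCA", "LCCA")]),
               "LSA")
})

test_that("outlet shares are invariant to a uniform impedance rescaling", {
  v <- fx_vessel("PRE")
  term <- distribute_rcr(rcr_params(1.2e7, 1.3e8, 1.1e-8),
                         dplyr::rename(outlet_areas(v), area = "area_m2"))
  net <- network_from_geometry(v, term)
  q <- fx_waveform()
  s1 <- solve_network(net, q)
  net2 <- net
  net2$segments$R <- net$segments$R * 3
  net2$terminals$Rp <- net$terminals$Rp * 3
  net2$terminals$Rd <- net$terminals$Rd * 3
  net2$terminals$C <- net$terminals$C / 3   # keep time constants
  s2 <- solve_network(net2, q)
  expect_equal(s2$outlet_summary$share_pct, s1$outlet_summary$share_pct,
               tolerance = 1e-9)
})

test_that("LSA flow and pressure drop are monotone in the origin narrowing", {
  sw <- lsa_narrowing_sweep(aorta_spec("PRE"), c(0, 0.3, 0.6, 0.8, 0.95),
                            fx_waveform(), pressure_targets(120, 80),
                            dt = 0.008)
  expect_true(all(diff(sw$lsa_share_pct) <= 1e-9))
  expect_true(all(diff(sw$dp_arch_lsa_mmHg) >= -1e-9))
  # near-occlusion starves the branch
  expect_lt(sw$lsa_share_pct[nrow(sw)], 0.1 * sw$lsa_share_pct[1])
})
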