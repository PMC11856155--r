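test_that("constant inflow settles to the purely resistive pressure", {
  qc <- flow_waveform(tgrid(0.85, 128), rep(100, 128), 0.85)  # 100 mL/s
  p <- rcr_params(1.24e8, 1.37e9, 9.96e-10)
  tr <- solve_rcr(p, qc, max_cycles = 80)
  expect_equal(max(tr$p_Pa), (p$Rp + p$Rd) * 1e-4, tolerance = 1e-8)
  expect_equal(min(tr$p_Pa), (p$Rp + p$Rd) * 1e-4, tolerance = 1e-8)
})

test_that("zero inflow decays exponentially with the distal time constant", {
  q0 <- flow_waveform(tgrid(0.85, 128), rep(0, 128), 0.85)
  p <- rcr_params(1.24e8, 1.37e9, 9.96e-10)
  tr <- solve_rcr(p, q0, p0 = 1e4, max_cycles = 1, min_cycles = 1,
                  require_convergence = FALSE)
  tau <- p$Rd * p$C
  expect_lt(max(abs(tr$p_Pa - 1e4 * exp(-tr$t_s / tau))) / 1e4, 1e-3)
})

test_that("sinusoidal inflow reproduces the closed-form impedance amplitude", {
  w <- 2 * pi / 0.85
  tt <- tgrid(0.85, 256)
  q <- flow_waveform(tt, 80 + 20 * sin(w * tt), 0.85)
  p <- rcr_params(1.24e8, 1.37e9, 9.96e-10)
  tr <- solve_rcr(p, q, max_cycles = 100)
  amp <- (max(tr$p_Pa) - min(tr$p_Pa)) / 2
  Z <- abs(p$Rp + p$Rd / (1 + 1i * w * p$Rd * p$C))
  expect_equal(amp, 20e-6 * Z, tolerance = 5e-3)
})

test_that("implicit stepping agrees with an adaptive high-order reference", {
  skip_if_not_installed("deSolve")
  set.seed(21)
  q <- fx_waveform()
  for (i in 1:3) {
    p <- rcr_params(stats::runif(1, 5e7, 3e8), stats::runif(1, 5e8, 3e9),
                    stats::runif(1, 5e-10, 3e-9))
    tau <- p$Rd * p$C
    tr <- solve_rcr(p, q, max_cycles = 100)
    rhs <- function(t, y, parms) {
      S <- (p$Rp + p$Rd) * pauhemo:::wf_interp_si(q, t) +
        p$Rp * p$Rd * p$C * pauhemo:::wf_deriv_si(q, t)
      list((S - y) / tau)
    }
    ref <- deSolve::ode(y = tr$p_Pa[1], times = c(tr$t_s, 0.85),
                        func = rhs, rtol = 1e-11, atol = 1e-4)
    n <- nrow(tr)
    expect_lt(max(abs(ref[1:n, 2] - tr$p_Pa)) / max(tr$p_Pa), 1e-3)
  }
})

test_that("time-step and convergence guards are enforced", {
  q <- fx_waveform()
  p <- rcr_params(1e8, 1e9, 1e-9)
  expect_error(solve_rcr(p, q, dt = 0.1), "T/50")
  expect_error(solve_rcr(p, q, max_cycles = 2, min_cycles = 2,
                         converge_tol = 1e-14),
               "did not reach periodic steady state")
  expect_error(rcr_params(-1, 1, 1), "strictly positive")
})

test_that("calibration round-trips a known reference parameter set", {
  # simulate with the published LCCA load of the first case, then recover
  p_true <- rcr_params(1.31e8, 1.44e9, 9.42e-10)
  q <- make_waveform(stroke_volume_mL = 5)
  tr <- solve_rcr(p_true, q, max_cycles = 100)
  gamma <- p_true$Rp / (p_true$Rp + p_true$Rd)
  cal <- calibrate_rcr(q, pressure_targets(max(tr$p_Pa), min(tr$p_Pa), "Pa"),
                       gamma = gamma)
  expect_equal(cal$Rp + cal$Rd, p_true$Rp + p_true$Rd, tolerance = 0.01)
  expect_equal(cal$C, p_true$C, tolerance = 0.05)
})

test_that("doubling both pressure targets doubles the recovered resistance", {
  q <- fx_waveform()
  t1 <- pressure_targets(120, 80)
  t2 <- pressure_targets(240, 160)
  c1 <- calibrate_rcr(q, t1)
  c2 <- calibrate_rcr(q, t2)
  expect_equal((c2$Rp + c2$Rd) / (c1$Rp + c1$Rd), 2, tolerance = 0.01)
})

test_that("pulseless calibration returns R directly and flags C", {
  qc <- flow_waveform(tgrid(0.85, 128), rep(80, 128), 0.85)
  p0 <- mmHg_to_Pa(93)
  expect_message(
    cal <- calibrate_rcr(qc, pressure_targets(p0, p0, "Pa"), gamma = 0.09),
    "unidentifiable")
  expect_equal(cal$Rp + cal$Rd, p0 / 80e-6, tolerance = 1e-6)
  expect_true(attr(cal, "unidentifiable_C"))
})

test_that("infeasible pulse-pressure demands abort with the achievable range", {
  q <- fx_waveform()
  expect_error(calibrate_rcr(q, pressure_targets(91, 90), gamma = 0.09),
               "achievable range")
})

test_that("area-ratio distribution follows the outlet-area rules", {
  g <- rcr_params(1e7, 1.1e8, 1e-8)
  one <- distribute_rcr(g, tibble::tibble(outlet = "DA", area = 3))
  expect_equal(one$Rp, g$Rp)
  expect_equal(one$Rd, g$Rd)
  expect_equal(one$C, g$C)
  two <- distribute_rcr(g, tibble::tibble(outlet = c("A", "B"), area = c(2, 2)))
  expect_equal(two$Rp, rep(2 * g$Rp, 2))
  expect_equal(two$Rd, rep(2 * g$Rd, 2))
  expect_equal(two$C, rep(g$C / 2, 2))
  expect_error(distribute_rcr(g, tibble::tibble(outlet = "A", area = 0)),
               "positive")
})

test_that("distribution recombines to the global load to machine precision", {
  g <- rcr_params(1.3e7, 1.4e8, 1.2e-8)
  set.seed(9)
  areas <- tibble::tibble(outlet = c("BCA", "LCCA", "LSA", "DA"),
                          area = stats::runif(4, 0.3, 4))
  d <- distribute_rcr(g, areas)
  expect_equal(1 / sum(1 / d$Rp), g$Rp, tolerance = 1e-12)
  expect_equal(1 / sum(1 / d$Rd), g$Rd, tolerance = 1e-12)
  expect_equal(sum(d$C), g$C, tolerance = 1e-12)
  # distal time constant is outlet-independent
  expect_equal(max(d$Rd * d$C) / min(d$Rd * d$C), 1, tolerance = 1e-12)
  rep <- validate_rcr_table(dplyr::mutate(d, case = "gen"))
  expect_lt(rep$spread_ratio, 1e-12)
  expect_lt(rep$spread_tau, 1e-12)
})

test_that("reference case tables are internally consistent where printed so", {
  tab <- rcr_reference_cases()
  expect_equal(nrow(tab), 12)
  rep <- validate_rcr_table(tab)
  # Rd/Rp split is uniform across outlets in all three cases
  expect_true(all(rep$spread_ratio < 0.02))
  # printed resistance and compliance ratios agree across columns
  case1 <- tab[tab$case == "CASE1", ]
  r_ratio <- case1$Rd[case1$outlet == "BCA"] / case1$Rd[case1$outlet == "LCCA"]
  c_ratio <- case1$C[case1$outlet == "LCCA"] / case1$C[case1$outlet == "BCA"]
  expect_equal(r_ratio, c_ratio, tolerance = 0.02)
})

test_that("a corrupted table cell is flagged with the violated relation", {
  g <- rcr_params(1e7, 1.1e8, 1e-8)
  d <- distribute_rcr(g, tibble::tibble(outlet = c("A", "B", "C", "D"),
                                        area = c(1, 2, 3, 4)))
  d$C[2] <- d$C[2] * 1.4
  rep <- validate_rcr_table(d)
  flags <- rep$flags[[1]]
  expect_true("B" %in% flags$outlet)
  expect_true("Rd*C" %in% flags$relation)
})
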