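test_that("Boltzmann gating function has midpoint, saturation and slope-sign behaviour", {
  expect_equal(gating_steady_state(-4.1, -43, -43), 0.5)
  expect_lt(abs(gating_steady_state(-4.1, -43, 100) - 1), 1e-10)
  # analytic inversion: value 0.1 at v_half + a*log(9) for inactivation
  expect_equal(gating_steady_state(5, -57, -57 + 5 * log(9)), 0.1,
               tolerance = 1e-12)
  # monotone: increasing iff a < 0
  v <- seq(-90, 20, by = 1)
  expect_true(all(diff(gating_steady_state(-7.8, -15, v)) > 0))
  expect_true(all(diff(gating_steady_state(7, -26, v)) < 0))
  expect_error(gating_steady_state(0, -40, -50), "non-zero")
})

test_that("h-current activation saturates at hyperpolarization and is 1/4 at its half-voltage", {
  k <- kinetics_constants()
  expect_lt(abs(mh_steady_state(-200, k) - 1), 1e-10)
  # exponents vanish at the half-voltage regardless of slope constants
  expect_equal(mh_steady_state(-52.1, k), 0.25)
  expect_equal(mh_steady_state(-52.1, kinetics_constants(mh_k1 = 1,
                                                         mh_k2 = 9)), 0.25)
  v <- seq(-100, 20, by = 0.5)
  expect_true(all(diff(mh_steady_state(v, k)) <= 0))
  vmid <- seq(-56, -44, by = 0.5)   # transition region of the curve
  expect_true(all(diff(mh_steady_state(vmid, k)) < 0))
  # time constant bounded in [0.5, 1.5] s and scaled multiplicatively
  tau <- mh_time_constant(v, 1, k)
  expect_true(all(tau >= 0.5 & tau <= 1.5))
  expect_equal(mh_time_constant(v, 50, k), 50 * tau)
})

test_that("voltage-dependent time constants are positive and fixed gate taus are exact", {
  set.seed(1)
  v <- stats::runif(1e4, -120, 60)
  taus <- gating_time_constants(v)
  expect_true(all(taus$tau_hNaF > 0))
  expect_true(all(taus$tau_mKDR > 0))
  expect_true(all(taus$tau_mCaS > 0))
  # both exponents vanish at -43 mV for the bell-shaped forms
  expect_equal(gating_time_constants(-43)$tau_hNaF, 0.03 / 2)
  expect_equal(gating_time_constants(-43)$tau_mKDR, 0.007 / 2)
})

test_that("Nernst reversal potentials follow the fixed and dynamic ion pools", {
  p <- canonical_params()
  expect_equal(reversal_potentials(p, 120)$ENa, 0)
  expect_equal(reversal_potentials(p, 12)$ENa, 26.45 * log(10))
  expect_equal(reversal_potentials(p, 15)$EK, 26.45 * log(9 / 130))
  expect_error(reversal_potentials(p, -1), "positive")
})

test_that("leak split reproduces the reference-potential construction", {
  EK <- 26.45 * log(9 / 130)
  ls <- leak_split(1.88, -55, 65, EK)
  expect_equal(ls$gLNa, 1.88 * (-55 - EK) / (65 - EK))
  expect_equal(ls$gLNa, 0.2166, tolerance = 1e-3)
  expect_equal(ls$gLK, 1.6634, tolerance = 1e-3)
  # identity gLNa + gLK = gL for arbitrary valid inputs
  set.seed(2)
  for (i in 1:20) {
    gL <- stats::runif(1, 0.1, 5)
    ELRef <- stats::runif(1, -65, -45)
    s <- leak_split(gL, ELRef, 65, EK)
    expect_equal(s$gLNa + s$gLK, gL, tolerance = 1e-12)
  }
  # limit case: ELRef at EK puts all leak on the K+ component
  expect_equal(leak_split(1.88, EK, 65, EK)$gLNa, 0)
  expect_error(leak_split(1, -55, EK, EK), "degenerate")
})

test_that("pump current is bounded, strictly increasing in Na+, with the printed half-activations", {
  p <- canonical_params()
  na <- seq(0.5, 80, by = 0.25)
  ip <- pump_current(na, p)
  expect_true(all(ip > 0 & ip < p$IPumpMax))
  expect_true(all(diff(ip) > 0))
  # half-activation at 25 mM times the constant K+ factor
  expect_equal(pump_current(25, p), 40.26 * 0.5 / (1 + exp(-3)),
               tolerance = 1e-12)
  expect_equal(pump_current(25, p), 19.174, tolerance = 1e-4)
  # K factor saturates for large extracellular K+
  psat <- hco_parameters(Ke = 1000)
  expect_equal(pump_current(25, psat), 40.26 / 2, tolerance = 1e-8)
})

test_that("membrane currents vanish with their driving forces and gates", {
  p <- canonical_params()
  EK <- p$EK
  st <- steady_state_cell(EK, nai = 15, params = p)
  cur <- membrane_currents(st, 0.5, p)
  expect_equal(cur$IKDR, 0)
  expect_equal(cur$IKA, 0)
  expect_equal(cur$IhK, 0)
  expect_equal(cur$ILK, 0)
  st2 <- steady_state_cell(-50, nai = 15, params = p)
  st2[["mh"]] <- 0
  cur2 <- membrane_currents(st2, 0, p)
  expect_equal(cur2$IhNa, 0)
  expect_equal(cur2$IhK, 0)
  # Na+/K+ split of the h-current: fixed 3:4 conductance ratio
  st3 <- steady_state_cell(-60, nai = 15, params = p)
  st3[["mh"]] <- 0.7
  cur3 <- membrane_currents(st3, 0, p)
  ENa <- reversal_potentials(p, 15)$ENa
  expect_equal(cur3$IhNa / cur3$IhK,
               (3 / 4) * (-60 - ENa) / (-60 - EK), tolerance = 1e-12)
  # pump always outward, synapse outward above its reversal
  expect_gt(cur3$IPump, 0)
  st4 <- steady_state_cell(-50, nai = 15, params = p)
  expect_gt(membrane_currents(st4, 0.5, p)$ISyn, 0)
})

test_that("compiled and reference vector fields agree to near machine precision", {
  p <- canonical_params()
  set.seed(3)
  for (i in 1:10) {
    y <- hco_state(
      steady_state_cell(stats::runif(1, -80, -20),
                        stats::runif(1, 10, 40), p),
      steady_state_cell(stats::runif(1, -80, -20),
                        stats::runif(1, 10, 40), p))
    # perturb gates off their steady states
    y[2:10] <- pmin(1, pmax(0, y[2:10] + stats::runif(9, -0.2, 0.2)))
    y[13:21] <- pmin(1, pmax(0, y[13:21] + stats::runif(9, -0.2, 0.2)))
    dr <- state_derivatives(y, p)
    dc <- deSolve::DLLfunc(y = as.numeric(y), dllname = "hcorhythm",
                           func = "hco_derivs", initfunc = "hco_init",
                           parms = hcorhythm:::.hcoParmVector(p, 2, FALSE),
                           times = 0)$dy
    expect_lt(max(abs(dr - dc) / (abs(dr) + 1e-9)), 1e-10)
  }
})

test_that("every gating derivative vanishes at its steady state", {
  p <- canonical_params()
  y <- steady_state_cell(-55, nai = 20, params = p)
  d <- state_derivatives(y, p)
  expect_true(all(abs(d[c(2:8, 10)]) < 1e-9))
})

test_that("the two-cell vector field is symmetric under cell exchange", {
  p <- canonical_params()
  c1 <- steady_state_cell(-48, 18, p)
  c2 <- steady_state_cell(-63, 26, p)
  d12 <- state_derivatives(hco_state(c1, c2), p)
  d21 <- state_derivatives(hco_state(c2, c1), p)
  expect_equal(unname(d12[1:11]), unname(d21[12:22]))
  expect_equal(unname(d12[12:22]), unname(d21[1:11]))
  # identical cells get identical derivatives
  dss <- state_derivatives(hco_state(c1, c1), p)
  expect_equal(unname(dss[1:11]), unname(dss[12:22]))
})

test_that("with the synapse removed the two-cell field restricts to the single-cell field", {
  p0 <- decouple(canonical_params())
  c1 <- steady_state_cell(-48, 18, p0)
  c2 <- steady_state_cell(-70, 30, p0)
  d2 <- state_derivatives(hco_state(c1, c2), p0)
  d1 <- state_derivatives(c1, p0)
  expect_equal(unname(d2[1:11]), unname(d1))
  expect_identical(decouple(p0)$gSyn, 0)
})

test_that("parameter validation rejects unphysical values and unknown fields", {
  expect_error(hco_parameters(gh = -1), "non-negative")
  expect_error(hco_parameters(C = 0), "positive")
  expect_error(hco_parameters(Ke = -9), "positive")
  expect_error(hco_parameters(M = -0.1), "M")
  expect_error(update_parameters(canonical_params(), nonsense = 1),
               "unknown")
  # derived constants recomputed on update
  p2 <- update_parameters(canonical_params(), gL = 3.76)
  expect_equal(p2$gLNa + p2$gLK, 3.76)
})
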