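test_that("decoupling zeroes the synapse and is idempotent", {
  p <- canonical_params()
  p0 <- decouple(p)
  expect_identical(p0$gSyn, 0)
  expect_equal(decouple(p0), p0)
  expect_equal(p0$gh, p$gh)
})

test_that("the decoupled single cell is episodic with much shorter episodes than the HCO", {
  m <- single_cell_metrics()
  expect_gte(nrow(m$episodes), 3)
  s <- m$summary
  ed_single <- s[s$metric == "ED", "mean"]
  expect_lt(ed_single, 5)              # episodes of a few bursts
  expect_gt(s[s$metric == "IEI", "mean"], 5)
  mh <- canonical_metrics()
  ed_hco <- mh$summary[mh$summary$metric == "ED", "mean"]
  expect_gt(ed_hco, ed_single)
})

test_that("the reduced constant-m_h model shows rest, coexistence and bursting zones and is never episodic", {
  sc <- reduced_scan()
  d <- sc$diagram
  expect_true(all(d$regime %in% c("rest", "coexistent", "bursting")))
  expect_true(any(d$regime == "rest"))
  expect_true(any(d$regime == "coexistent"))
  # ordering: bursting-only threshold above the coexistence lower bound
  expect_gt(sc$rest_hi, sc$burst_lo)
  # boundaries are interior to the scanned interval
  expect_gt(sc$burst_lo, min(d$mh))
  expect_lt(sc$rest_hi, max(d$mh))
  # the bursting branch carries finite BD/IBI values
  br <- d[d$burst_label == "bursting", ]
  expect_true(all(is.finite(br$mean_bd)))
  expect_true(all(br$mean_bd > 0.05 & br$mean_bd < 1))
})

test_that("m_h spans both reduced-model boundaries during full single-cell episodic cycling", {
  sc <- reduced_scan()
  tr <- single_cell_trace()
  mh <- trace_channel(tr, "mh")
  expect_lt(min(mh), sc$burst_lo)
  expect_gt(max(mh), sc$rest_hi)
})

test_that("equilibrium finder reaches a genuine fixed point with a meaningful spectrum", {
  p <- canonical_params()
  s <- rest_state_stability(p, 0.5)
  d <- cell_deriv_residual(s$state, p)
  expect_lt(d, 1e-8)
  expect_length(s$eigenvalues, 10)
  expect_true(s$stable)
})

test_that("the rest state loses stability through a complex pair as m_h grows", {
  p <- canonical_params()
  lo <- rest_state_stability(p, 0.80)
  hi <- rest_state_stability(p, 0.99, start = lo$state)
  expect_true(lo$stable)
  expect_false(hi$stable)
  expect_true(hi$oscillatory)   # Hopf, not a real-eigenvalue crossing
  h <- hopf_point(p, 0.80, 0.99, resolution = 0.002)
  expect_gt(h$mh_hopf, 0.80)
  expect_lt(h$mh_hopf, 0.99)
})

test_that("scaling tau_h by 1 reproduces the plain single-cell run", {
  r1 <- scaled_tau_run(scale = 1, transient = 30, record = 20)
  p0 <- decouple(canonical_params())
  ref <- integrate_hco(p0, init = canonical_ic(p0, 1), transient = 30,
                       record = 20, sample_dt = 5e-4)
  expect_equal(r1$trace$channels, ref$channels)
})
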