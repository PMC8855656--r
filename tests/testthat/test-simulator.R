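test_that("zero vector field leaves voltage and sodium constant", {
  p <- hco_parameters(gNaF = 0, gNaP = 0, gKDR = 0, gKA = 0, gh = 0,
                      gCaS = 0, gL = 0, gSyn = 0, IPumpMax = 0, M = 0)
  ic <- canonical_ic(p)
  tr <- integrate_hco(p, init = ic, transient = 0, record = 2,
                      sample_dt = 1e-3)
  expect_equal(max(abs(trace_channel(tr, "Vm.1") - ic[["Vm.1"]])), 0,
               tolerance = 1e-9)
  expect_equal(max(abs(trace_channel(tr, "Nai.2") - 15)), 0,
               tolerance = 1e-9)
})

test_that("integration is deterministic", {
  p <- hco_parameters()
  tr1 <- integrate_hco(p, transient = 2, record = 3, sample_dt = 5e-4)
  tr2 <- integrate_hco(p, transient = 2, record = 3, sample_dt = 5e-4)
  expect_identical(tr1$channels, tr2$channels)
})

test_that("recorded samples respect the gating box and sodium bounds", {
  tr <- canonical_trace()
  for (ch in c("mh.1", "mh.2")) {
    x <- trace_channel(tr, ch)
    expect_true(all(x >= 0 & x <= 1))
  }
  for (ch in c("Nai.1", "Nai.2")) {
    x <- trace_channel(tr, ch)
    expect_true(all(x > 0 & x < 2 * tr$params$Nae))
  }
})

test_that("gating variables stay in [0,1] from perturbed initial gates", {
  p <- hco_parameters()
  set.seed(4)
  ic <- canonical_ic(p)
  ic[c(2:10, 13:21)] <- stats::runif(18)   # arbitrary gate values
  tr <- integrate_hco(p, init = ic, transient = 0, record = 3,
                      sample_dt = 5e-4, channels = "all")
  gates <- tr$channels[, grepl("^(h|m)", colnames(tr$channels))]
  expect_true(all(gates >= -1e-9 & gates <= 1 + 1e-9))
})

test_that("tightening solver tolerances preserves spike count and times", {
  # short window: the episodic attractor is chaotic, so solver
  # comparisons are only meaningful before trajectories decorrelate
  p <- hco_parameters()
  base <- integrate_hco(p, transient = 0, record = 5, sample_dt = 2e-4)
  tight <- integrate_hco(p, transient = 0, record = 5,
                         sample_dt = 2e-4,
                         solver = solver_config(abs_tol = 1e-9,
                                                rel_tol = 1e-10))
  s1 <- detect_spikes(base$time, trace_channel(base, "Vm.1"))
  s2 <- detect_spikes(tight$time, trace_channel(tight, "Vm.1"))
  expect_equal(length(s1), length(s2))
  if (length(s1)) expect_lt(max(abs(s1 - s2)), 2e-3)
})

test_that("a fixed-step RK4 integration reproduces the adaptive solution over a short window", {
  p <- hco_parameters()
  tr <- integrate_hco(p, transient = 20, record = 0.5, sample_dt = 2e-4,
                      channels = "all")
  # re-integrate the same 3 s from the post-transient state two ways
  start <- tr$channels[1, ]
  parms <- hcorhythm:::.hcoParmVector(p, 2, FALSE)
  tt <- seq(0, 3, by = 2e-4)
  ad <- deSolve::ode(y = start, times = tt, func = "hco_derivs",
                     parms = parms, dllname = "hcorhythm",
                     initfunc = "hco_init",
                     method = deSolve::rkMethod("rk45dp7"),
                     atol = 1e-8, rtol = 1e-9, hini = 1e-8, hmax = 0.05,
                     maxsteps = 1e8)
  fx <- deSolve::ode(y = start, times = tt, func = "hco_derivs",
                     parms = parms, dllname = "hcorhythm",
                     initfunc = "hco_init", method = "rk4", hini = 1e-5)
  sa <- detect_spikes(tt, ad[, 2])
  sf <- detect_spikes(tt, fx[, 2])
  expect_equal(length(sa), length(sf))
  if (length(sa)) expect_lt(max(abs(sa - sf)), 2e-3)
})

test_that("resampling refuses upsampling, preserves constants and is near-lossless at 2x", {
  p <- hco_parameters(gNaF = 0, gNaP = 0, gKDR = 0, gKA = 0, gh = 0,
                      gCaS = 0, gL = 0, gSyn = 0, IPumpMax = 0)
  tr <- integrate_hco(p, transient = 0, record = 1, sample_dt = 5e-4)
  expect_error(resample_trace(tr, 1e-4), "upsampling")
  same <- resample_trace(tr, 5e-4)
  expect_identical(same$channels, tr$channels)
  down <- resample_trace(tr, 1e-3)
  expect_true(all(abs(trace_channel(down, "Vm.1") - (-50)) < 1e-9))
  # mean voltage preserved under 2x downsampling of a spiking trace
  trc <- canonical_trace()
  d2 <- resample_trace(trc, 1e-3)
  expect_lt(abs(mean(trace_channel(d2, "Vm.1")) -
                mean(trace_channel(trc, "Vm.1"))), 0.5)
})

test_that("invalid initial states are rejected with informative errors", {
  p <- hco_parameters()
  expect_error(integrate_hco(p, init = c(-50, 0.5, 12)), "length 11")
  expect_error(integrate_hco(p, transient = -1), "transient")
  expect_error(integrate_hco(p, sample_dt = 0.01), "sample_dt")
})
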