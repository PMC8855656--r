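# Shared fixtures.  Expensive simulations are memoised so several test
# files can reuse one run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

canonical_params <- function(...) hco_parameters(...)

# canonical HCO simulation, scaled-down protocol (used by several files)
canonical_trace <- function() {
  memo("canonical_trace", integrate_hco(
    canonical_params(), transient = 500, record = 4000,
    sample_dt = 5e-4))
}

canonical_metrics <- function() {
  memo("canonical_metrics", {
    tr <- canonical_trace()
    attr(classify_regime(tr, "Vm.1"), "metrics")
  })
}

# decoupled single cell, scaled-down protocol
single_cell_trace <- function() {
  memo("single_cell_trace", {
    p <- decouple(canonical_params())
    integrate_hco(p, init = steady_state_cell(-50, 15, p),
                  transient = 400, record = 500, sample_dt = 5e-4)
  })
}

single_cell_metrics <- function() {
  memo("single_cell_metrics", {
    tr <- single_cell_trace()
    attr(classify_regime(tr, "Vm", single_cell_config()), "metrics")
  })
}

# residual of the single-cell vector field at a putative equilibrium
# (the frozen mh slot is excluded)
cell_deriv_residual <- function(state, params) {
  d <- state_derivatives(state, decouple(params))
  max(abs(d[-9]))
}

# coarse reduced constant-m_h scan shared by reduced-model tests
reduced_scan <- function() {
  memo("reduced_scan", scan_constant_mh(
    canonical_params(), grid = seq(0.72, 1, by = 0.02),
    transient = 20, record = 12, resolution = 0.005))
}
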