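#' Boltzmann steady-state gating function
#'
#' `1 / (1 + exp((vm - v_half)/a))`.  Negative `a` gives an activation curve
#' (increasing in `vm`), positive `a` an inactivation curve; the value is
#' 0.5 at `vm = v_half`.
#'
#' @param a slope factor (mV), non-zero.
#' @param v_half half-(in)activation voltage (mV).
#' @param vm membrane potential (mV); vectorised.
#' @return Gating fraction(s) in (0, 1).
#' @export
gating_steady_state <- function(a, v_half, vm) {
  if (!is.numeric(a) || length(a) != 1 || is.na(a) || a == 0) {
    stop("slope factor 'a' must be a single non-zero number", call. = FALSE)
  }
  1 / (1 + exp((vm - v_half) / a))
}

#' h-current activation: steady state and time constant
#'
#' The steady-state activation of the hyperpolarization-activated h-current
#' uses a double-exponential Boltzmann-like form that fully activates on
#' hyperpolarization and equals exactly 1/4 at its half-voltage; the time
#' constant is sigmoid in voltage and bounded between `tauh_base` and
#' `tauh_base + tauh_amp` seconds (0.5 and 1.5 s by default), times
#' `tau_h_scale`.
#'
#' @param vm membrane potential (mV); vectorised.
#' @param kinetics a [kinetics_constants()] table.
#' @param tau_h_scale dimensionless multiplier on the time constant.
#' @return `mh_steady_state`: activation fraction(s) in (0, 1];
#'   `mh_time_constant`: time constant(s) in seconds.
#' @export
mh_steady_state <- function(vm, kinetics = kinetics_constants()) {
  x <- vm - kinetics$mh_vhalf
  1 / (1 + 2 * exp(kinetics$mh_k1 * x) + exp(kinetics$mh_k2 * x))
}

#' @rdname mh_steady_state
#' @export
mh_time_constant <- function(vm, tau_h_scale = 1,
                             kinetics = kinetics_constants()) {
  tau_h_scale * (kinetics$tauh_base + kinetics$tauh_amp /
    (1 + exp(kinetics$tauh_slope * (vm - kinetics$tauh_vhalf))))
}

#' Voltage-dependent gating time constants
#'
#' Bell-shaped time constants (s) for fast-Na+ inactivation,
#' delayed-rectifier activation and slow-Ca2+ activation.  All remaining
#' gates relax with fixed time constants: mNaP 0.001 s, hNaP 0.1 s,
#' hKA 0.02 s, hCaS 0.34 s, mSyn 0.05 s.
#'
#' @param vm membrane potential (mV); vectorised.
#' @param kinetics a [kinetics_constants()] table.
#' @return A list with components `tau_hNaF`, `tau_mKDR`, `tau_mCaS`
#'   (seconds, all positive).
#' @export
gating_time_constants <- function(vm, kinetics = kinetics_constants()) {
  x43 <- vm + 43
  tau_hNaF <- 0.03 / (exp(x43 / kinetics$thNaF_s1) +
                      exp(x43 / kinetics$thNaF_s2))
  tau_mKDR <- 0.007 / (exp(x43 / kinetics$thKDR_s1) +
                       exp(x43 / kinetics$thKDR_s2))
  x1 <- vm + 48.01
  x2 <- vm + 51.01
  if (kinetics$tCaS_mode < 0.5) {
    A <- ifelse(abs(x1) < 1e-7, 0.02 * 4.5, 0.02 * x1 / (1 - exp(-x1 / 4.5)))
    B <- ifelse(abs(x2) < 1e-7, 0.05 * 4.5, 0.05 * x2 / (exp(x2 / 4.5) - 1))
    tau_mCaS <- kinetics$tCaS_scale * 0.001 / (A + B)
  } else {
    tau_mCaS <- kinetics$tCaS_scale *
      (0.001 + 0.02 / (1 + exp(x1 / 4.5)) + 0.05 / (1 + exp(x2 / 4.5)))
  }
  list(tau_hNaF = tau_hNaF, tau_mKDR = tau_mKDR, tau_mCaS = tau_mCaS)
}

#' Nernst reversal potentials
#'
#' `ENa = RTF * log(Nae/nai)` follows the dynamic intracellular Na+;
#' `EK = RTF * log(Ke/Ki)` is constant because both K+ concentrations are
#' fixed parameters.
#'
#' @param params an [hco_parameters()] object.
#' @param nai intracellular Na+ (mM), > 0; vectorised.
#' @return List with `ENa` and `EK` (mV).
#' @export
reversal_potentials <- function(params, nai) {
  if (any(!is.finite(nai)) || any(nai <= 0)) {
    stop("intracellular [Na+] must be positive and finite", call. = FALSE)
  }
  list(ENa = params$RTF * log(params$Nae / nai), EK = params$EK)
}

#' Split the total leak conductance into Na+ and K+ components
#'
#' The split is chosen so that the total leak current vanishes at the
#' reference leak reversal `ELRef` when ENa equals its reference `ENaRef`:
#' `gLNa = gL*(ELRef - EK)/(ENaRef - EK)` and
#' `gLK = gL*(ELRef - ENaRef)/(EK - ENaRef)`; the two components always sum
#' to `gL`.
#'
#' @param gL total leak conductance (nS).
#' @param ELRef reference leak reversal (mV), between `EK` and `ENaRef`.
#' @param ENaRef reference Na+ reversal (mV).
#' @param EK K+ reversal (mV).
#' @return List with `gLNa` and `gLK` (nS).
#' @export
leak_split <- function(gL, ELRef, ENaRef, EK) {
  if (ENaRef == EK) {
    stop("degenerate reversal potentials: ENaRef equals EK", call. = FALSE)
  }
  list(gLNa = gL * (ELRef - EK) / (ENaRef - EK),
       gLK = gL * (ELRef - ENaRef) / (EK - ENaRef))
}

#' Na+/K+ ATPase pump current
#'
#' Sigmoid activation by intracellular Na+ (half-activation 25 mM, slope
#' 3 mM) times a constant extracellular-K+ factor (half-activation 6 mM):
#' `IPump = IPumpMax / (1 + exp((25 - nai)/3)) / (1 + exp(6 - Ke))`.
#' Always positive (outward), strictly increasing in `nai`, bounded by
#' `IPumpMax`.
#'
#' @param nai intracellular Na+ (mM), > 0; vectorised.
#' @param params an [hco_parameters()] object.
#' @return Pump current (pA).
#' @export
pump_current <- function(nai, params) {
  if (any(nai <= 0)) stop("nai must be positive", call. = FALSE)
  params$IPumpMax * params$pump_K_factor / (1 + exp((25 - nai) / 3))
}

#' Neuron state vector
#'
#' The 11 state variables of one model cell, in the canonical order used
#' throughout the package (and by the compiled vector field).
#'
#' @param Vm membrane potential (mV).
#' @param hNaF,mNaP,hNaP,mKDR,hKA,mCaS,hCaS,mh,mSyn gating fractions in
#'   `[0, 1]`.
#' @param Nai intracellular Na+ (mM), > 0.
#' @return Named numeric vector of length 11.
#' @export
neuron_state <- function(Vm, hNaF, mNaP, hNaP, mKDR, hKA, mCaS, hCaS,
                         mh, mSyn, Nai) {
  y <- c(Vm = Vm, hNaF = hNaF, mNaP = mNaP, hNaP = hNaP, mKDR = mKDR,
         hKA = hKA, mCaS = mCaS, hCaS = hCaS, mh = mh, mSyn = mSyn,
         Nai = Nai)
  g <- y[2:10]
  if (any(g < 0 | g > 1)) {
    stop("gating fractions must lie in [0, 1]", call. = FALSE)
  }
  if (Nai <= 0) stop("Nai must be positive", call. = FALSE)
  y
}

#' Neuron state with all gates at steady state for a given voltage
#'
#' @param vm membrane potential (mV).
#' @param nai intracellular Na+ (mM).
#' @param params an [hco_parameters()] object.
#' @return Named numeric state vector of length 11 (see [neuron_state()]).
#' @export
steady_state_cell <- function(vm, nai = 15, params = hco_parameters()) {
  k <- params$kinetics
  neuron_state(
    Vm = vm,
    hNaF = gating_steady_state(k$hNaF_slope, k$hNaF_vhalf, vm),
    mNaP = gating_steady_state(-4.1, -43, vm),
    hNaP = gating_steady_state(5, -57, vm),
    mKDR = gating_steady_state(-15, -18, vm),
    hKA = gating_steady_state(5, -59.8, vm),
    mCaS = gating_steady_state(-4.27, -45.6, vm),
    hCaS = gating_steady_state(0.86, -56.34, vm),
    mh = mh_steady_state(vm, k),
    mSyn = gating_steady_state(-0.4, -25, vm),
    Nai = nai
  )
}

#' Two-cell (half-center oscillator) state
#'
#' @param cell1,cell2 length-11 state vectors from [neuron_state()] or
#'   [steady_state_cell()].
#' @return Named numeric vector of length 22 with suffixes `.1` and `.2`.
#' @export
hco_state <- function(cell1, cell2) {
  stopifnot(length(cell1) == 11, length(cell2) == 11)
  y <- c(cell1, cell2)
  names(y) <- c(paste0(names(cell1), ".1"), paste0(names(cell2), ".2"))
  y
}

#' Instantaneous membrane currents of one cell
#'
#' Evaluates every membrane current (pA, positive outward) from a cell
#' state and the presynaptic release variable.  Fast-Na+ and A-type
#' activations are instantaneous (`m_inf` at the current voltage); the
#' h-current conductance is split 3/7 (Na+) to 4/7 (K+) with shared
#' squared activation.
#'
#' @param state length-11 cell state (see [neuron_state()]).
#' @param mSyn_pre presynaptic release variable in `[0, 1]` (0 for a
#'   decoupled cell).
#' @param params an [hco_parameters()] object.
#' @return Named list of currents: `INaF`, `INaP`, `IKDR`, `IKA`, `IhNa`,
#'   `IhK`, `ICaS`, `ILNa`, `ILK`, `IPump`, `ISyn` (pA).
#' @export
membrane_currents <- function(state, mSyn_pre = 0,
                              params = hco_parameters()) {
  V <- state[["Vm"]]
  rev <- reversal_potentials(params, state[["Nai"]])
  ENa <- rev$ENa
  EK <- rev$EK
  mNaF <- gating_steady_state(-7.8, -15, V)
  mKA <- gating_steady_state(-10, -20, V)
  list(
    INaF = params$gNaF * mNaF^3 * state[["hNaF"]] * (V - ENa),
    INaP = params$gNaP * state[["mNaP"]] * state[["hNaP"]] * (V - ENa),
    IKDR = params$gKDR * state[["mKDR"]]^4 * (V - EK),
    IKA = params$gKA * mKA * state[["hKA"]] * (V - EK),
    IhNa = (3 / 7) * params$gh * state[["mh"]]^2 * (V - ENa),
    IhK = (4 / 7) * params$gh * state[["mh"]]^2 * (V - EK),
    ICaS = params$gCaS * state[["mCaS"]]^3 * state[["hCaS"]] *
      (V - params$ECa),
    ILNa = params$gLNa * (V - ENa),
    ILK = params$gLK * (V - EK),
    IPump = pump_current(state[["Nai"]], params),
    ISyn = params$gSyn * mSyn_pre * (V - params$ESyn)
  )
}

# Reference (pure-R) right-hand side for one cell.  Kept deliberately
# independent of the compiled RHS: it recomposes the derivatives from
# membrane_currents() and the gating functions, and is used in tests as an
# internal-consistency oracle against the C kernel.
cell_derivatives_r <- function(state, mSyn_pre, params) {
  V <- state[["Vm"]]
  cur <- membrane_currents(state, mSyn_pre, params)
  k <- params$kinetics
  taus <- gating_time_constants(V, k)
  dV <- -Reduce(`+`, cur) / params$C
  d <- c(
    Vm = dV,
    hNaF = (gating_steady_state(k$hNaF_slope, k$hNaF_vhalf, V) -
              state[["hNaF"]]) / taus$tau_hNaF,
    mNaP = (gating_steady_state(-4.1, -43, V) - state[["mNaP"]]) / 0.001,
    hNaP = (gating_steady_state(5, -57, V) - state[["hNaP"]]) / 0.1,
    mKDR = (gating_steady_state(-15, -18, V) - state[["mKDR"]]) /
      taus$tau_mKDR,
    hKA = (gating_steady_state(5, -59.8, V) - state[["hKA"]]) / 0.02,
    mCaS = (gating_steady_state(-4.27, -45.6, V) - state[["mCaS"]]) /
      taus$tau_mCaS,
    hCaS = (gating_steady_state(0.86, -56.34, V) - state[["hCaS"]]) / 0.34,
    mh = (mh_steady_state(V, k) - state[["mh"]]) /
      mh_time_constant(V, params$tau_h_scale, k),
    mSyn = (gating_steady_state(-0.4, -25, V) - state[["mSyn"]]) / 0.05,
    Nai = params$M * (params$Nae - state[["Nai"]]) -
      params$alpha * (cur$IhNa + cur$ILNa + cur$INaF + cur$INaP +
                        3 * cur$IPump)
  )
  d
}

#' State derivatives of the full two-cell system (reference implementation)
#'
#' Pure-R composition of the vector field from [membrane_currents()] and
#' the gating kinetics.  The compiled kernel used by [integrate_hco()] is a
#' separate implementation of the same equations; the two are
#' cross-checked in the test suite.  Each cell's synaptic current is driven
#' by the other cell's `mSyn`.
#'
#' @param state length-22 HCO state (see [hco_state()]), or length-11 for a
#'   single decoupled cell.
#' @param params an [hco_parameters()] object.
#' @return Named numeric vector of derivatives, same length as `state`.
#' @export
state_derivatives <- function(state, params = hco_parameters()) {
  if (length(state) == 11) {
    return(cell_derivatives_r(stats::setNames(state, .cell_names), 0, params))
  }
  stopifnot(length(state) == 22)
  c1 <- stats::setNames(state[1:11], .cell_names)
  c2 <- stats::setNames(state[12:22], .cell_names)
  d <- c(cell_derivatives_r(c1, c2[["mSyn"]], params),
         cell_derivatives_r(c2, c1[["mSyn"]], params))
  stats::setNames(d, names(state))
}

.cell_names <- c("Vm", "hNaF", "mNaP", "hNaP", "mKDR", "hKA", "mCaS",
                 "hCaS", "mh", "mSyn", "Nai")
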