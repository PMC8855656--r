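#' Model parameters for the half-center oscillator
#'
#' Constructs the full parameter record of the conductance-based half-center
#' oscillator (HCO): two identical, mutually inhibitory neurons, each with
#' fast and persistent Na+ currents, delayed-rectifier and A-type K+
#' currents, a low-threshold slow Ca2+ current, a hyperpolarization-activated
#' mixed-cation h-current (split 3/7 Na+ : 4/7 K+), split Na+/K+ leak,
#' an intracellular-Na+-activated Na+/K+ ATPase pump current, and inhibitory
#' graded synaptic coupling.  Defaults are the canonical values at which the
#' model produces episodic bursting.
#'
#' Unit system: mV, s, nS, pA, nF, mM (so nS*mV = pA and pA/nF = mV/s).
#'
#' @param C membrane capacitance (nF).
#' @param gNaF,gNaP,gKDR,gKA,gh,gCaS,gL,gSyn maximal conductances (nS).
#' @param ECa Ca2+ reversal potential (mV; Ca2+ concentrations are not
#'   modelled, so this is fixed).
#' @param ELRef reference leak reversal potential (mV) used to split the
#'   total leak conductance into Na+ and K+ components.
#' @param ENaRef reference Na+ reversal potential (mV) used for the same
#'   split (the running ENa follows intracellular Na+).
#' @param ESyn synaptic reversal potential (mV; inhibitory).
#' @param IPumpMax maximal Na+/K+ pump current (pA).
#' @param Nae extracellular Na+ (mM, fixed).
#' @param Ke,Ki extra-/intracellular K+ (mM, fixed), giving a constant EK.
#' @param M monensin rate constant (1/s): first-order Na+ influx
#'   proportional to (Nae - Nai), emulating the Na+/H+ antiporter monensin.
#'   0 unless monensin is applied.
#' @param alpha conversion factor from net Na+ current to d[Na+]i/dt
#'   (mM/pA/s), equal to 1/(v*F) for intracellular volume v.
#' @param tau_h_scale dimensionless multiplier on the h-current activation
#'   time constant (>= 1; 50 in the slow single-cell protocol).
#' @param RTF Nernst slope RT/F (mV).
#' @param kinetics list of kinetics constants, see [kinetics_constants()].
#' @return An object of class `hco_parameters`: a named list with the above
#'   fields plus derived constants `EK` (mV), `gLNa`/`gLK` (nS, the leak
#'   split) and `pump_K_factor` (the constant extracellular-K+ activation
#'   factor of the pump).
#' @examples
#' p <- hco_parameters()
#' p$gLNa + p$gLK == p$gL
#' @export
hco_parameters <- function(C = 0.001,
                           gNaF = 105, gNaP = 4.97, gKDR = 79, gKA = 1.13,
                           gh = 0.34, gCaS = 3.3, gL = 1.88, gSyn = 1.02,
                           ECa = 160, ELRef = -55, ENaRef = 65, ESyn = -70,
                           IPumpMax = 40.26,
                           Nae = 120, Ke = 9, Ki = 130,
                           M = 0,
                           alpha = 4.682255338155292,
                           tau_h_scale = 1,
                           RTF = 26.45,
                           kinetics = kinetics_constants()) {
  p <- list(C = C, gNaF = gNaF, gNaP = gNaP, gKDR = gKDR, gKA = gKA,
            gh = gh, gCaS = gCaS, gL = gL, gSyn = gSyn,
            ECa = ECa, ELRef = ELRef, ENaRef = ENaRef, ESyn = ESyn,
            IPumpMax = IPumpMax, Nae = Nae, Ke = Ke, Ki = Ki,
            M = M, alpha = alpha, tau_h_scale = tau_h_scale, RTF = RTF,
            kinetics = kinetics)
  validate_hco_parameters(p)
  p$EK <- RTF * log(Ke / Ki)
  ls <- leak_split(gL, ELRef, ENaRef, p$EK)
  p$gLNa <- ls$gLNa
  p$gLK <- ls$gLK
  p$pump_K_factor <- 1 / (1 + exp(6 - Ke))
  structure(p, class = "hco_parameters")
}

#' Kinetics constants of the gating equations
#'
#' Collects, in one named table, the numeric constants of the voltage
#' dependence of the h-current activation and of the bell-shaped gating time
#' constants.  These are exposed (rather than hard-coded) because they
#' parameterise forms for which reasonable variants exist in the source
#' model family; the defaults are the values at which the canonical model
#' exhibits its reference episodic rhythm.
#'
#' The h-current steady-state activation is
#' `mh_inf(V) = 1 / (1 + 2*exp(mh_k1*(V - mh_vhalf)) + exp(mh_k2*(V - mh_vhalf)))`
#' (slopes in 1/mV; strictly decreasing in V; equals 1/4 at `mh_vhalf`), and
#' its time constant is
#' `tau_h(V) = tauh_base + tauh_amp / (1 + exp(tauh_slope*(V - tauh_vhalf)))`
#' seconds, multiplied by the model's `tau_h_scale`.
#'
#' @param mh_k1,mh_k2 slope constants of `mh_inf` (1/mV).
#' @param mh_vhalf voltage offset of `mh_inf` (mV).
#' @param tauh_base,tauh_amp,tauh_slope,tauh_vhalf constants of `tau_h`
#'   (s, s, 1/mV, mV).
#' @param hNaF_slope,hNaF_vhalf Boltzmann constants of fast-Na+
#'   inactivation steady state (mV).
#' @param thNaF_s1,thNaF_s2 exponential slopes (mV) of the bell-shaped
#'   `tau_hNaF(V) = 0.03 / (exp((V+43)/thNaF_s1) + exp((V+43)/thNaF_s2))`.
#' @param thKDR_s1,thKDR_s2 exponential slopes (mV) of the analogous
#'   `tau_mKDR(V) = 0.007 / (exp((V+43)/thKDR_s1) + exp((V+43)/thKDR_s2))`.
#' @param tCaS_scale dimensionless multiplier on the slow-Ca2+ activation
#'   time constant.
#' @param tCaS_mode voltage-dependence form of the slow-Ca2+ activation
#'   time constant: 0 for the alpha/beta rate form, 1 for the sigmoid-sum
#'   form (slow subthreshold activation).
#' @return A named list of class `hco_kinetics`.
#' @export
kinetics_constants <- function(mh_k1 = 2.26, mh_k2 = 6.15,
                               mh_vhalf = -52.1,
                               tauh_base = 0.5, tauh_amp = 1,
                               tauh_slope = 0.1, tauh_vhalf = -53.23,
                               hNaF_slope = 7, hNaF_vhalf = -26,
                               thNaF_s1 = 15, thNaF_s2 = -16,
                               thKDR_s1 = 40, thKDR_s2 = -50,
                               tCaS_scale = 1, tCaS_mode = 0) {
  structure(list(mh_k1 = mh_k1, mh_k2 = mh_k2, mh_vhalf = mh_vhalf,
                 tauh_base = tauh_base, tauh_amp = tauh_amp,
                 tauh_slope = tauh_slope, tauh_vhalf = tauh_vhalf,
                 hNaF_slope = hNaF_slope, hNaF_vhalf = hNaF_vhalf,
                 thNaF_s1 = thNaF_s1, thNaF_s2 = thNaF_s2,
                 thKDR_s1 = thKDR_s1, thKDR_s2 = thKDR_s2,
                 tCaS_scale = tCaS_scale, tCaS_mode = tCaS_mode),
            class = "hco_kinetics")
}

validate_hco_parameters <- function(p) {
  conds <- c("gNaF", "gNaP", "gKDR", "gKA", "gh", "gCaS", "gL", "gSyn")
  for (g in conds) {
    if (!is.numeric(p[[g]]) || length(p[[g]]) != 1 || is.na(p[[g]]) ||
        p[[g]] < 0) {
      stop("conductance '", g, "' must be a single non-negative number",
           call. = FALSE)
    }
  }
  if (p$C <= 0) stop("capacitance C must be positive", call. = FALSE)
  for (ion in c("Nae", "Ke", "Ki")) {
    if (p[[ion]] <= 0) {
      stop("concentration '", ion, "' must be positive", call. = FALSE)
    }
  }
  if (p$M < 0) stop("monensin rate constant M must be >= 0", call. = FALSE)
  if (p$tau_h_scale <= 0) stop("tau_h_scale must be positive", call. = FALSE)
  EK <- p$RTF * log(p$Ke / p$Ki)
  if (p$ENaRef == EK) {
    stop("degenerate reversal potentials: ENaRef equals EK", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.hco_parameters <- function(x, ...) {
  cat("Half-center oscillator parameters (units: mV, s, nS, pA, nF, mM)\n")
  num <- vapply(x, is.numeric, logical(1))
  v <- unlist(x[num])
  cat(paste0("  ", format(names(v), width = 14), format(v, digits = 10),
             collapse = "\n"), "\n")
  invisible(x)
}

#' Update a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, revalidated,
#' and with derived constants (EK, leak split, pump K+ factor) recomputed.
#'
#' @param params an [hco_parameters()] object.
#' @param ... named scalar fields to replace (e.g. `gh = 0.36`).
#' @return A new `hco_parameters` object.
#' @export
update_parameters <- function(params, ...) {
  stopifnot(inherits(params, "hco_parameters"))
  repl <- list(...)
  base <- unclass(params)
  base$EK <- base$gLNa <- base$gLK <- base$pump_K_factor <- NULL
  unknown <- setdiff(names(repl), names(base))
  if (length(unknown)) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base[names(repl)] <- repl
  do.call(hco_parameters, base)
}
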