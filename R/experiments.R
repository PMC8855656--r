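#' Sweep a model parameter and classify the regime at each value
#'
#' Reproduces the one-at-a-time parameter-variation protocols: for each
#' grid value the model is integrated past a transient from the canonical
#' initial condition, the activity regime is classified (silence /
#' episodic / continuous / mixed) and the rhythm metrics are summarised.
#'
#' @param name parameter to sweep: one of `"gh"`, `"IPumpMax"`, `"M"`,
#'   `"gSyn"`, `"tau_h_scale"`.
#' @param grid numeric vector of parameter values.
#' @param params base [hco_parameters()].
#' @param transient,record integration protocol per grid point (s).
#' @param config an [analysis_config()].
#' @param ncell 2 for the HCO, 1 for the decoupled cell.
#' @return An object of class `sweep_result`: data.frame with one row per
#'   grid value: `value`, `regime`, `n_episodes`, `mean_EP`, `cv_EP`,
#'   `mean_ED`, `mean_IEI`, `mean_BP`, `mean_BD`, `mean_IBI`, `failed`.
#' @export
parameter_sweep <- function(name = c("gh", "IPumpMax", "M", "gSyn",
                                     "tau_h_scale"),
                            grid,
                            params = hco_parameters(),
                            transient = 1000, record = 500,
                            config = analysis_config(),
                            ncell = 2) {
  name <- match.arg(name)
  empty <- data.frame(value = numeric(0), regime = character(0),
                      n_episodes = integer(0), mean_EP = numeric(0),
                      cv_EP = numeric(0), mean_ED = numeric(0),
                      mean_IEI = numeric(0), mean_BP = numeric(0),
                      mean_BD = numeric(0), mean_IBI = numeric(0),
                      failed = logical(0))
  rows <- lapply(grid, function(v) {
    a <- list(params)
    a[[name]] <- v
    p <- do.call(update_parameters, a)
    tr <- tryCatch(
      integrate_hco(p, init = canonical_ic(p, ncell), transient = transient,
                    record = record, sample_dt = 5e-4),
      error = function(e) e)
    if (inherits(tr, "error")) {
      return(data.frame(value = v, regime = "failed", n_episodes = NA,
                        mean_EP = NA, cv_EP = NA, mean_ED = NA,
                        mean_IEI = NA, mean_BP = NA, mean_BD = NA,
                        mean_IBI = NA, failed = TRUE))
    }
    ch <- if (ncell == 2) "Vm.1" else "Vm"
    lab <- classify_regime(tr, ch, config)
    m <- attr(lab, "metrics")
    s <- m$summary
    g <- function(met, col = "mean") s[s$metric == met, col]
    data.frame(value = v, regime = as.character(lab),
               n_episodes = nrow(m$episodes),
               mean_EP = g("EP"), cv_EP = g("EP", "cv"), mean_ED = g("ED"),
               mean_IEI = g("IEI"), mean_BP = g("BP"), mean_BD = g("BD"),
               mean_IBI = g("IBI"), failed = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else empty
  structure(list(parameter = name, table = out, params = params,
                 transient = transient, record = record),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Parameter sweep over", x$parameter, "\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Locate a regime boundary by bisection
#'
#' Bisects a parameter interval on the classified regime, assuming
#' `from_label` at `lo` and `to_label` at `hi`.  Probes use a shortened
#' transient; a confirmation run with a longer transient is performed at
#' the final midpoint and a widened bracket is reported if it disagrees.
#'
#' @param name swept parameter (see [parameter_sweep()]).
#' @param lo,hi interval endpoints.
#' @param from_label,to_label expected regime labels at `lo` / `hi`
#'   (either order along the axis is allowed).
#' @param resolution bisection stopping width (parameter units).
#' @param params base [hco_parameters()].
#' @param transient,record probe protocol (s).
#' @param confirm_transient transient for the confirmation run (s); 0
#'   skips confirmation.
#' @param config an [analysis_config()].
#' @param ncell 2 for the HCO, 1 for the single cell.
#' @return List with `boundary` (midpoint), `bracket` (c(lo, hi)),
#'   `confirmed` (logical or NA), and `probes` (data.frame of value,
#'   label).
#' @export
regime_boundary <- function(name, lo, hi, from_label, to_label,
                            resolution = 0.001,
                            params = hco_parameters(),
                            transient = 1000, record = 400,
                            confirm_transient = 0,
                            config = analysis_config(),
                            ncell = 2) {
  classify_at <- function(v, tran) {
    a <- list(params)
    a[[name]] <- v
    p <- do.call(update_parameters, a)
    tr <- integrate_hco(p, init = canonical_ic(p, ncell),
                        transient = tran, record = record,
                        sample_dt = 5e-4)
    ch <- if (ncell == 2) "Vm.1" else "Vm"
    as.character(classify_regime(tr, ch, config))
  }
  l_lo <- classify_at(lo, transient)
  l_hi <- classify_at(hi, transient)
  probes <- data.frame(value = c(lo, hi), label = c(l_lo, l_hi))
  if (l_lo != from_label || l_hi != to_label) {
    stop(sprintf(
      "no bracket: expected '%s' at %g (got '%s') and '%s' at %g (got '%s')",
      from_label, lo, l_lo, to_label, hi, l_hi), call. = FALSE)
  }
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    l_mid <- classify_at(mid, transient)
    probes <- rbind(probes, data.frame(value = mid, label = l_mid))
    if (l_mid == from_label) lo <- mid else hi <- mid
  }
  boundary <- (lo + hi) / 2
  confirmed <- NA
  if (confirm_transient > 0) {
    l_conf <- classify_at(boundary, confirm_transient)
    confirmed <- l_conf %in% c(from_label, to_label)
  }
  list(boundary = boundary, bracket = c(lo, hi), confirmed = confirmed,
       probes = probes)
}

#' Probe a parameter point for bistability with two initial conditions
#'
#' Runs the classifier from two initial states at identical parameters;
#' the point is bistable when the labels differ (e.g. silence from a
#' rest-like start, continuous bursting from a bursting start, as found
#' at low maximal pump currents).
#'
#' @param params an [hco_parameters()] object.
#' @param ic_rest,ic_burst the two initial states (length 22 for the HCO).
#' @param transient,record protocol (s).
#' @param config an [analysis_config()].
#' @return List with `label_rest`, `label_burst`, `bistable`.
#' @export
bistability_probe <- function(params,
                              ic_rest = NULL, ic_burst = NULL,
                              transient = 500, record = 300,
                              config = analysis_config()) {
  if (is.null(ic_rest)) {
    c1 <- steady_state_cell(-55, nai = 23, params = params)
    ic_rest <- hco_state(c1, steady_state_cell(-55.5, nai = 23,
                                               params = params))
  }
  if (is.null(ic_burst)) {
    # continue a state from the canonical bursting attractor: the most
    # reliable bursting-like start for probing coexistence
    base <- hco_parameters(kinetics = params$kinetics)
    seed_tr <- integrate_hco(base, transient = 40, record = 1,
                             sample_dt = 5e-4, channels = "all")
    ic_burst <- seed_tr$channels[nrow(seed_tr$channels), ]
  }
  lab <- function(ic) {
    tr <- integrate_hco(params, init = ic, transient = transient,
                        record = record, sample_dt = 5e-4)
    as.character(classify_regime(tr, "Vm.1", config))
  }
  l1 <- lab(ic_rest)
  l2 <- lab(ic_burst)
  list(label_rest = l1, label_burst = l2, bistable = (l1 != l2))
}

#' Monensin experiment: paired canonical runs with and without Na+ influx
#'
#' Monensin (a Na+/H+ antiporter) is modelled as a first-order Na+ influx
#' with rate constant `M` (1/s); it raises intracellular Na+ and thereby
#' indirectly increases the pump current.  Runs the canonical protocol at
#' `M = 0` and at the given `M` and reports both metric sets and their
#' differences.
#'
#' @param params base [hco_parameters()] (the `M = 0` reference).
#' @param M monensin rate constant (1/s) for the treated run.
#' @param transient,record protocol (s).
#' @param config an [analysis_config()].
#' @return List with `control`, `treated` (each a `rhythm_metrics`), and
#'   `delta` (data.frame of mean EP/ED/IEI and EP-CV changes).
#' @export
monensin_experiment <- function(params = hco_parameters(), M = 0.002,
                                transient = 5000, record = 2000,
                                config = analysis_config()) {
  stopifnot(M >= 0)
  run1 <- function(p) {
    tr <- integrate_hco(p, transient = transient, record = record,
                        sample_dt = 5e-4)
    attr(classify_regime(tr, "Vm.1", config), "metrics")
  }
  ctrl <- run1(update_parameters(params, M = 0))
  trt <- run1(update_parameters(params, M = M))
  pick <- function(m, met, col = "mean") {
    m$summary[m$summary$metric == met, col]
  }
  delta <- data.frame(
    metric = c("EP", "ED", "IEI", "EP_CV"),
    control = c(pick(ctrl, "EP"), pick(ctrl, "ED"), pick(ctrl, "IEI"),
                pick(ctrl, "EP", "cv")),
    treated = c(pick(trt, "EP"), pick(trt, "ED"), pick(trt, "IEI"),
                pick(trt, "EP", "cv")))
  delta$change <- delta$treated - delta$control
  list(control = ctrl, treated = trt, delta = delta, M = M)
}

#' Overlay intra-episode bursts of a slow full model on the reduced diagram
#'
#' For each intra-episode burst cycle of a (typically tau_h-scaled)
#' single-cell trace, pairs the cycle's mean m_h with its burst duration
#' and interburst interval, and computes residuals against the reduced
#' constant-m_h model's BD/IBI curves at the nearest diagram m_h.
#'
#' @param trace an `hco_trace` of a single-cell run (must include `mh`).
#' @param diagram an `mh_bifurcation` from [scan_constant_mh()].
#' @param config an [analysis_config()] for the fast rhythm.
#' @return data.frame with one row per burst cycle: `mh_mean`, `bd`,
#'   `ibi`, `diagram_mh`, `diagram_bd`, `diagram_ibi`, `bd_residual`,
#'   `ibi_residual`; rows with m_h outside the diagram's bursting branch
#'   are dropped (attribute `n_outside` counts them).
#' @export
bifurcation_overlay <- function(trace, diagram,
                                config = single_cell_config()) {
  m <- analyze_vm(trace$time, trace_channel(trace, "Vm"), config)
  mh <- trace_channel(trace, "mh")
  d <- diagram$diagram
  branch <- d[d$burst_label == "bursting" & is.finite(d$mean_bd), ]
  if (!nrow(branch)) stop("diagram has no bursting branch", call. = FALSE)
  out <- NULL
  n_outside <- 0L
  b <- m$bursts
  for (e in seq_len(nrow(m$episodes))) {
    i0 <- m$episodes$first_burst[e]
    i1 <- m$episodes$last_burst[e]
    if (i1 <= i0) next
    for (k in i0:(i1 - 1)) {
      # burst cycle: onset_k to onset_{k+1}
      sel <- trace$time >= b$onset[k] & trace$time < b$onset[k + 1]
      mh_mean <- mean(mh[sel])
      if (mh_mean < min(branch$mh) || mh_mean > max(branch$mh)) {
        n_outside <- n_outside + 1L
        next
      }
      j <- which.min(abs(branch$mh - mh_mean))
      bd <- b$offset[k] - b$onset[k]
      ibi <- b$onset[k + 1] - b$offset[k]
      out <- rbind(out, data.frame(
        mh_mean = mh_mean, bd = bd, ibi = ibi,
        diagram_mh = branch$mh[j],
        diagram_bd = branch$mean_bd[j], diagram_ibi = branch$mean_ibi[j],
        bd_residual = bd - branch$mean_bd[j],
        ibi_residual = ibi - branch$mean_ibi[j]))
    }
  }
  if (is.null(out)) out <- data.frame()
  attr(out, "n_outside") <- n_outside
  out
}
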