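#' Solver configuration
#'
#' Settings of the adaptive embedded Runge-Kutta integration.  The default
#' method is deSolve's Dormand-Prince 5(4) pair (`"rk45dp7"`), the
#' highest-order embedded explicit pair in deSolve with a dense-output
#' (continuous interpolation) path, which the model's very fast spikes and
#' fine output grids make essential; tolerances default to values tight
#' enough that halving them changes spike times by far less than a sample
#' interval.
#'
#' @param abs_tol absolute error tolerance.
#' @param rel_tol relative error tolerance.
#' @param initial_step initial step size (s).
#' @param method a deSolve method tag or [deSolve::rkMethod()] name.
#' @param max_step maximal step size (s).
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(abs_tol = 1e-8, rel_tol = 1e-9,
                          initial_step = 1e-8, method = "rk45dp7",
                          max_step = 0.05) {
  stopifnot(abs_tol > 0, rel_tol > 0, initial_step > 0, max_step > 0)
  structure(list(abs_tol = abs_tol, rel_tol = rel_tol,
                 initial_step = initial_step, method = method,
                 max_step = max_step),
            class = "solver_config")
}

# Flat parameter vector consumed by the compiled kernel; the slot order
# must match the #defines in src/hco_model.c.
.hcoParmVector <- function(params, ncell, mh_frozen = FALSE) {
  k <- params$kinetics
  c(params$C, params$gNaF, params$gNaP, params$gKDR, params$gKA,
    params$gh, params$gCaS, params$gSyn,
    params$ECa, params$ESyn,
    params$IPumpMax, params$Nae, params$M, params$alpha,
    params$tau_h_scale, params$RTF,
    params$EK, params$gLNa, params$gLK, params$pump_K_factor,
    k$mh_k1, k$mh_k2, k$mh_vhalf,
    k$tauh_base, k$tauh_amp, k$tauh_slope, k$tauh_vhalf,
    k$hNaF_slope, k$hNaF_vhalf, k$thNaF_s1, k$thNaF_s2,
    k$thKDR_s1, k$thKDR_s2, k$tCaS_scale, k$tCaS_mode,
    ncell, as.numeric(mh_frozen))
}

#' Canonical initial condition
#'
#' The model is exactly symmetric under exchange of the two cells, so a
#' symmetric initial state would remain symmetric forever in exact
#' arithmetic; the canonical initial condition therefore breaks symmetry by
#' starting the two cells at different voltages (-50 and -60 mV), each with
#' all gates at steady state for its own voltage and `Nai = 15` mM.
#'
#' @param params an [hco_parameters()] object.
#' @param ncell 2 for the HCO, 1 for a decoupled cell (uses cell 1 only).
#' @return A state vector of length 22 (or 11).
#' @export
canonical_ic <- function(params = hco_parameters(), ncell = 2) {
  c1 <- steady_state_cell(-50, nai = 15, params = params)
  if (ncell == 1) return(c1)
  hco_state(c1, steady_state_cell(-60, nai = 15, params = params))
}

#' Integrate the half-center oscillator (or single-cell) model
#'
#' Runs the compiled vector field with an adaptive embedded Runge-Kutta
#' solver, discards a transient, and returns the post-transient window
#' sampled on a uniform grid.  The model is fully deterministic: identical
#' inputs give identical traces.
#'
#' @param params an [hco_parameters()] object.
#' @param init initial state: length 22 for the HCO, length 11 for a
#'   decoupled single cell (defaults to [canonical_ic()]).
#' @param transient seconds to integrate and discard before recording
#'   (5000 s in the reference protocol; shorter values are appropriate for
#'   scan probes).
#' @param record seconds to record after the transient.
#' @param solver a [solver_config()].
#' @param sample_dt uniform output sampling interval (s), at most 1e-3
#'   (spikes are milliseconds wide).
#' @param channels which state channels to keep: `"analysis"` keeps Vm,
#'   mh and Nai per cell (sufficient for all rhythm metrics), `"all"`
#'   keeps the full state.
#' @param mh_frozen logical; freeze `mh` at its initial value (the reduced
#'   constant-m_h model).
#' @param chunk integration chunk length (s) used to bound memory for long
#'   records.
#' @return An object of class `hco_trace`: a list with `time` (s), a
#'   numeric matrix `channels` (one row per sample), `sample_dt`, `ncell`,
#'   `params`, `solver`, `transient`, `init`.
#' @export
integrate_hco <- function(params = hco_parameters(),
                          init = NULL,
                          transient = 5000, record = 2000,
                          solver = solver_config(),
                          sample_dt = 5e-4,
                          channels = c("analysis", "all"),
                          mh_frozen = FALSE,
                          chunk = 250) {
  channels <- match.arg(channels)
  stopifnot(transient >= 0, record > 0, sample_dt > 0, sample_dt <= 1e-3)
  if (is.null(init)) init <- canonical_ic(params)
  ncell <- if (length(init) == 22) 2 else if (length(init) == 11) 1 else
    stop("init must have length 11 (single cell) or 22 (HCO)", call. = FALSE)
  nm <- if (ncell == 2) {
    c(paste0(.cell_names, ".1"), paste0(.cell_names, ".2"))
  } else .cell_names
  y <- stats::setNames(as.numeric(init), nm)
  parms <- .hcoParmVector(params, ncell, mh_frozen)
  method <- solver$method
  if (is.character(method) && method %in% deSolve::rkMethod()) {
    method <- deSolve::rkMethod(method)
  }

  step_fun <- function(y0, t0, t1, times = NULL) {
    if (is.null(times)) times <- c(t0, t1)
    out <- deSolve::ode(y = y0, times = times, func = "hco_derivs",
                        parms = parms, dllname = "hcorhythm",
                        initfunc = "hco_init",
                        method = method,
                        atol = solver$abs_tol, rtol = solver$rel_tol,
                        hini = solver$initial_step, hmax = solver$max_step,
                        maxsteps = 1e8)
    if (any(!is.finite(out[nrow(out), -1]))) {
      stop("integration failure: non-finite state near t = ",
           signif(out[nrow(out), 1], 6), " s", call. = FALSE)
    }
    out
  }

  # transient: integrate in coarse chunks, keep only the final state
  t_now <- 0
  while (t_now < transient - 1e-9) {
    t_next <- min(t_now + chunk, transient)
    out <- step_fun(y, t_now, t_next)
    y <- out[nrow(out), -1]
    t_now <- t_next
  }

  keep <- if (channels == "all") nm else {
    nm[grepl("^(Vm|mh|Nai)", nm)]
  }
  n_total <- floor(record / sample_dt)
  mat <- matrix(NA_real_, nrow = n_total + 1, ncol = length(keep),
                dimnames = list(NULL, keep))
  time <- seq(0, by = sample_dt, length.out = n_total + 1)
  filled <- 1
  mat[1, ] <- y[keep]
  t_now <- 0
  while (filled <= n_total) {
    n_chunk <- min(ceiling(chunk / sample_dt), n_total - filled + 1)
    tt <- seq(t_now, by = sample_dt, length.out = n_chunk + 1)
    out <- step_fun(y, t_now, tt[length(tt)], times = tt)
    mat[(filled + 1):(filled + n_chunk), ] <-
      out[-1, keep, drop = FALSE]
    y <- out[nrow(out), -1]
    t_now <- tt[length(tt)]
    filled <- filled + n_chunk
  }

  structure(list(time = time, channels = mat, sample_dt = sample_dt,
                 ncell = ncell, params = params, solver = solver,
                 transient = transient, init = init,
                 mh_frozen = mh_frozen),
            class = "hco_trace")
}

#' @export
print.hco_trace <- function(x, ...) {
  cat(sprintf(
    "hco_trace: %d cell(s), %.6g s at dt = %.3g s (%d samples), %s\n",
    x$ncell, x$time[length(x$time)], x$sample_dt, length(x$time),
    paste(colnames(x$channels), collapse = ", ")))
  invisible(x)
}

#' Extract a channel from a trace
#'
#' @param trace an `hco_trace`.
#' @param name channel name, e.g. `"Vm.1"` (or `"Vm"` for a single cell).
#' @return Numeric vector.
#' @export
trace_channel <- function(trace, name) {
  if (!name %in% colnames(trace$channels)) {
    stop("no channel '", name, "' in trace (have: ",
         paste(colnames(trace$channels), collapse = ", "), ")",
         call. = FALSE)
  }
  trace$channels[, name]
}

#' Downsample a trace by linear interpolation
#'
#' @param trace an `hco_trace`.
#' @param new_dt new sampling interval (s), at least the native one
#'   (upsampling is refused).
#' @return A new `hco_trace` on the coarser uniform grid.
#' @export
resample_trace <- function(trace, new_dt) {
  if (new_dt < trace$sample_dt - 1e-15) {
    stop("upsampling refused: new_dt (", new_dt,
         ") is finer than the native sampling interval (",
         trace$sample_dt, ")", call. = FALSE)
  }
  if (isTRUE(all.equal(new_dt, trace$sample_dt))) return(trace)
  t_new <- seq(trace$time[1], trace$time[length(trace$time)], by = new_dt)
  mat <- apply(trace$channels, 2, function(ch) {
    stats::approx(trace$time, ch, xout = t_new)$y
  })
  out <- trace
  out$time <- t_new
  out$channels <- mat
  out$sample_dt <- new_dt
  out
}
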