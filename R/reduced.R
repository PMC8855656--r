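#' Decouple the half-center oscillator into a single cell
#'
#' Sets the synaptic conductance to zero; all other parameters are kept.
#' Idempotent.
#'
#' @param params an [hco_parameters()] object.
#' @return A new `hco_parameters` object with `gSyn = 0`.
#' @export
decouple <- function(params) {
  update_parameters(params, gSyn = 0)
}

#' Single-cell run with a scaled h-current time constant
#'
#' Integrates the decoupled single cell with `tau_h_scale` applied to the
#' h-current activation time constant.  With a large scale factor (50 in
#' the reference protocol) the episodic rhythm slows dramatically — much
#' longer episode durations and interepisode intervals — while the
#' intra-episode burst characteristics change little, reflecting the
#' leading role of the slow variable m_h.
#'
#' @param params an [hco_parameters()] object (synapse removed internally).
#' @param scale multiplier on tau_h (>= 1).
#' @param transient,record,sample_dt integration protocol, see
#'   [integrate_hco()].
#' @param config an [analysis_config()]; defaults to the single-cell
#'   segmentation settings [single_cell_config()].
#' @return List with `trace` (an `hco_trace`) and `metrics`
#'   (a `rhythm_metrics`).
#' @export
scaled_tau_run <- function(params = hco_parameters(), scale = 50,
                           transient = 2000, record = 1500,
                           sample_dt = 5e-4,
                           config = single_cell_config()) {
  stopifnot(scale >= 1)
  p <- update_parameters(decouple(params), tau_h_scale = scale)
  tr <- integrate_hco(p, init = canonical_ic(p, ncell = 1),
                      transient = transient, record = record,
                      sample_dt = sample_dt)
  m <- analyze_vm(tr$time, trace_channel(tr, "Vm"), config)
  list(trace = tr, metrics = m)
}

#' Segmentation settings for single-cell (and reduced-model) traces
#'
#' The decoupled cell bursts much faster than the coupled half-center
#' oscillator (interburst intervals of ~0.1 s versus ~0.5-0.6 s), so its
#' burst gap threshold must sit between its intra-burst inter-spike
#' intervals (< 0.02 s) and its interburst intervals, rather than at the
#' 0.3 s used for the HCO.
#'
#' @param isi_gap,episode_gap,... overrides passed to [analysis_config()].
#' @return An `analysis_config`.
#' @export
single_cell_config <- function(isi_gap = 0.05, episode_gap = 4, ...) {
  analysis_config(isi_gap = isi_gap, episode_gap = episode_gap, ...)
}

#' Scan the reduced constant-m_h model over a grid of m_h values
#'
#' In the reduced model the h-current activation m_h is frozen as a
#' parameter of the decoupled single cell.  At each grid value the model
#' is simulated from two initial conditions — one rest-like, and one
#' bursting-like continued from the previous grid point of a downward
#' sweep — and classified.  The reduced model exhibits only two regimes
#' (rest and continuous bursting), possibly coexisting; it is never
#' episodic.
#'
#' @param params an [hco_parameters()] object (synapse removed internally).
#' @param grid increasing vector of m_h values in `[0, 1]`.
#' @param transient,record per-point integration protocol (s).
#' @param config an [analysis_config()] for the fast reduced rhythm.
#' @param rest_ic optional rest-like initial state (length 11).
#' @param refine logical: bisection-refine the two regime boundaries.
#' @param resolution bisection resolution in m_h for `refine`.
#' @return An object of class `mh_bifurcation`: a data.frame (`diagram`)
#'   with columns `mh`, `rest_label`, `burst_label`, `regime`
#'   (rest / bursting / coexistent), `vmax`, `vmin`, `mean_bd`, `mean_ibi`
#'   of the bursting orbit, plus boundary estimates `burst_lo` (smallest
#'   m_h with a bursting attractor) and `rest_hi` (largest m_h with a
#'   stable rest state).
#' @export
scan_constant_mh <- function(params = hco_parameters(),
                             grid = seq(0.7, 1, by = 0.005),
                             transient = 25, record = 15,
                             config = single_cell_config(episode_gap = 2),
                             rest_ic = NULL, refine = TRUE,
                             resolution = 0.001) {
  p <- decouple(params)
  grid <- sort(grid)
  if (any(grid < 0 | grid > 1)) stop("m_h grid must lie in [0, 1]",
                                     call. = FALSE)
  if (is.null(rest_ic)) {
    rest_ic <- steady_state_cell(-55, nai = 23, params = p)
  }

  run_pt <- function(ic, mh, keep_state = FALSE) {
    ic[["mh"]] <- mh
    tr <- tryCatch(
      integrate_hco(p, init = ic, transient = transient, record = record,
                    sample_dt = 5e-4, mh_frozen = TRUE,
                    channels = if (keep_state) "all" else "analysis"),
      error = function(e) e)
    if (inherits(tr, "error")) return(list(label = "failed", trace = NULL))
    lab <- classify_regime(tr, "Vm", config)
    # the reduced model is bistable rest/continuous; any recurring
    # bursting counts as the bursting regime
    m <- attr(lab, "metrics")
    lab2 <- if (lab %in% c("continuous", "episodic", "mixed") &&
                nrow(m$bursts) >= 3) "bursting" else "rest"
    list(label = lab2, metrics = m, trace = tr)
  }

  n <- length(grid)
  rest_label <- burst_label <- character(n)
  vmax <- vmin <- mean_bd <- mean_ibi <- rep(NA_real_, n)

  # rest branch: simulate from the continued rest equilibrium, mildly
  # perturbed (+0.5 mV), so the label reflects local stability rather
  # than the basin geometry around an arbitrary rest-like state
  eq_start <- NULL
  rest_probe_ic <- function(mh) {
    eq <- tryCatch(rest_state_stability(params, mh, start = eq_start),
                   error = function(e) NULL)
    if (!is.null(eq)) {
      eq_start <<- eq$state
      ic <- eq$state
      ic[["Vm"]] <- ic[["Vm"]] + 0.5
      ic
    } else rest_ic
  }
  for (i in seq_len(n)) {
    rest_label[i] <- run_pt(rest_probe_ic(grid[i]), grid[i])$label
  }
  # bursting branch: downward continuation from the top of the grid
  ic <- steady_state_cell(-30, nai = 35, params = p)
  for (i in rev(seq_len(n))) {
    r <- run_pt(ic, grid[i], keep_state = TRUE)
    burst_label[i] <- r$label
    if (r$label == "bursting") {
      v <- trace_channel(r$trace, "Vm")
      vmax[i] <- max(v)
      vmin[i] <- min(v)
      s <- r$metrics$summary
      mean_bd[i] <- s[s$metric == "BD", "mean"]
      mean_ibi[i] <- s[s$metric == "IBI", "mean"]
      ic <- r$trace$channels[nrow(r$trace$channels), ]
    } else if (r$label == "failed") {
      next
    } else {
      break  # bursting attractor lost; lower grid points get the rest IC
    }
  }
  burst_label[burst_label == ""] <- "rest"

  regime <- ifelse(burst_label == "bursting" & rest_label == "rest",
                   "coexistent",
            ifelse(burst_label == "bursting" | rest_label == "bursting",
                   "bursting", "rest"))

  bisect <- function(lo, hi, test) {
    while (hi - lo > resolution) {
      mid <- (lo + hi) / 2
      if (test(mid)) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }

  # boundary below which the bursting attractor disappears
  ib <- which(burst_label == "bursting")
  burst_lo <- if (length(ib) && min(ib) > 1) {
    i0 <- min(ib)
    state0 <- NULL
    ic_b <- steady_state_cell(-30, nai = 35, params = p)
    r0 <- run_pt(ic_b, grid[i0], keep_state = TRUE)
    cont_ic <- if (!is.null(r0$trace)) {
      r0$trace$channels[nrow(r0$trace$channels), ]
    } else ic_b
    if (refine) {
      bisect(grid[i0 - 1], grid[i0], function(mh) {
        run_pt(cont_ic, mh)$label == "bursting"
      })
    } else grid[i0]
  } else if (length(ib)) grid[min(ib)] else NA_real_

  # boundary above which the rest state is no longer an attractor
  ir <- which(rest_label == "rest")
  rest_hi <- if (length(ir) && max(ir) < n) {
    i1 <- max(ir)
    if (refine) {
      bisect(grid[i1], grid[i1 + 1], function(mh) {
        run_pt(rest_probe_ic(mh), mh)$label != "rest"
      })
    } else grid[i1]
  } else if (length(ir)) grid[max(ir)] else NA_real_

  structure(list(
    diagram = data.frame(mh = grid, rest_label = rest_label,
                         burst_label = burst_label, regime = regime,
                         vmax = vmax, vmin = vmin, mean_bd = mean_bd,
                         mean_ibi = mean_ibi),
    burst_lo = burst_lo, rest_hi = rest_hi,
    params = p, transient = transient, record = record),
    class = "mh_bifurcation")
}

#' @export
print.mh_bifurcation <- function(x, ...) {
  tab <- table(x$diagram$regime)
  cat("Reduced constant-m_h bifurcation scan over [",
      min(x$diagram$mh), ",", max(x$diagram$mh), "]\n")
  print(tab)
  cat(sprintf("bursting attractor disappears below m_h ~ %.3f\n",
              x$burst_lo))
  cat(sprintf("rest state loses stability above  m_h ~ %.3f\n", x$rest_hi))
  invisible(x)
}

#' Equilibrium and linear stability of the reduced constant-m_h model
#'
#' Finds the rest equilibrium of the decoupled single cell with m_h frozen
#' (10 free state variables; the frozen m_h and the decoupled mSyn drop
#' out of the Jacobian), by damped Newton iteration on the vector field
#' with a numerically differenced Jacobian (central differences, steps
#' scaled to each variable).  Stability is read from the eigenvalues; the
#' Andronov-Hopf point is where the leading complex pair's real part
#' crosses zero.
#'
#' @param params an [hco_parameters()] object (synapse removed internally).
#' @param mh frozen m_h value in `[0, 1]`.
#' @param start optional length-11 starting state (e.g. the previous
#'   grid point's equilibrium, for continuation).
#' @param tol Newton tolerance on the maximal derivative magnitude.
#' @return List with `state` (length-11 equilibrium, mh slot = `mh`),
#'   `eigenvalues` (complex, of the 10x10 Jacobian), `max_re` (largest
#'   real part), `stable`, `oscillatory` (leading eigenvalue complex).
#' @export
rest_state_stability <- function(params = hco_parameters(), mh,
                                 start = NULL, tol = 1e-9) {
  stopifnot(mh >= 0, mh <= 1)
  p <- decouple(params)
  if (is.null(start)) start <- steady_state_cell(-55, nai = 23, params = p)
  start[["mh"]] <- mh
  free <- setdiff(seq_len(11), 9)  # all but the frozen mh
  fn <- function(x) {
    st <- start
    st[free] <- x
    cell_derivatives_r(st, 0, p)[free]
  }
  x <- as.numeric(start[free])
  jac_num <- function(x) {
    J <- matrix(0, length(x), length(x))
    for (j in seq_along(x)) {
      h <- 1e-6 * max(abs(x[j]), 1e-3)
      xp <- x; xp[j] <- x[j] + h
      xm <- x; xm[j] <- x[j] - h
      J[, j] <- (fn(xp) - fn(xm)) / (2 * h)
    }
    J
  }
  converged <- FALSE
  for (it in 1:80) {
    f <- fn(x)
    if (max(abs(f)) < tol) { converged <- TRUE; break }
    J <- jac_num(x)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      xn <- x + lambda * step
      nai_slot <- length(xn)   # Nai is the last free variable
      ok <- is.finite(xn[nai_slot]) && xn[nai_slot] > 0 &&
        all(is.finite(fn(xn)))
      if (ok && (max(abs(fn(xn))) < max(abs(f)) || lambda < 1e-4)) break
      lambda <- lambda / 2
      if (lambda < 1e-12) { xn <- x; break }
    }
    x <- xn
  }
  if (!converged && max(abs(fn(x))) > 1e-6) {
    stop("no equilibrium found for m_h = ", mh,
         " (continuation gap); residual ", signif(max(abs(fn(x))), 3),
         call. = FALSE)
  }
  J <- jac_num(x)
  ev <- eigen(J, only.values = TRUE)$values
  eq <- start
  eq[free] <- x
  list(state = eq, eigenvalues = ev, max_re = max(Re(ev)),
       stable = max(Re(ev)) < 0,
       oscillatory = abs(Im(ev[which.max(Re(ev))])) > 1e-8)
}

#' Locate the Andronov-Hopf bifurcation of the reduced model
#'
#' Bisects on the sign of the leading eigenvalue real part of the rest
#' equilibrium as m_h varies, with continuation of the equilibrium between
#' evaluations.
#'
#' @param params an [hco_parameters()] object.
#' @param lo,hi bracketing m_h values (rest stable at `lo`, unstable at
#'   `hi`).
#' @param resolution bisection resolution in m_h.
#' @return List with `mh_hopf`, the bracketing interval, and the leading
#'   eigenvalue pair at each end.
#' @export
hopf_point <- function(params = hco_parameters(), lo = 0.7, hi = 1,
                       resolution = 0.001) {
  s_lo <- rest_state_stability(params, lo)
  s_hi <- rest_state_stability(params, hi, start = s_lo$state)
  if (!s_lo$stable || s_hi$stable) {
    stop("no Hopf bracket: rest stable at lo and unstable at hi required",
         call. = FALSE)
  }
  start <- s_lo$state
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    s <- rest_state_stability(params, mid, start = start)
    start <- s$state
    if (s$stable) lo <- mid else hi <- mid
  }
  list(mh_hopf = (lo + hi) / 2, lo = lo, hi = hi)
}
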