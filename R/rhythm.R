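#' Analysis configuration for spike/burst/episode segmentation
#'
#' Defaults follow the separation of time scales in the model: spikes
#' overshoot 0 mV while subthreshold inter-episode oscillations stay well
#' below -20 mV; intra-burst inter-spike intervals are far below 0.3 s
#' while intra-episode inter-burst intervals are ~0.4-0.6 s; and
#' inter-episode intervals (~tens of seconds) dwarf the 4 s episode gap.
#'
#' @param spike_threshold spike detection threshold (mV), upward crossing.
#' @param refractory minimal inter-spike interval (s).
#' @param isi_gap maximal intra-burst inter-spike interval (s).
#' @param min_spikes minimal spikes per burst.
#' @param episode_gap maximal intra-episode inter-burst gap (s).
#' @param min_bursts minimal bursts per episode.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(spike_threshold = -20, refractory = 0.003,
                            isi_gap = 0.3, min_spikes = 2,
                            episode_gap = 4, min_bursts = 2) {
  stopifnot(isi_gap > refractory, episode_gap > isi_gap)
  structure(list(spike_threshold = spike_threshold, refractory = refractory,
                 isi_gap = isi_gap, min_spikes = min_spikes,
                 episode_gap = episode_gap, min_bursts = min_bursts),
            class = "analysis_config")
}

#' Detect spikes by upward threshold crossing
#'
#' One spike per upward crossing of the threshold; crossings within the
#' refractory period of the previous accepted spike are ignored.  Spike
#' times are the (interpolated) crossing times.
#'
#' @param time uniform time grid (s).
#' @param vm membrane potential samples (mV).
#' @param threshold detection threshold (mV).
#' @param refractory minimal inter-spike interval (s).
#' @return Numeric vector of strictly increasing spike times (s).
#' @export
detect_spikes <- function(time, vm, threshold = -20, refractory = 0.003) {
  stopifnot(length(time) == length(vm))
  if (length(time) > 2) {
    dt <- diff(time)
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
      stop("detect_spikes requires a uniform time grid", call. = FALSE)
    }
  }
  above <- vm >= threshold
  idx <- which(!above[-length(above)] & above[-1]) # crossing between idx, idx+1
  if (!length(idx)) return(numeric(0))
  # linear interpolation of the crossing time
  frac <- (threshold - vm[idx]) / (vm[idx + 1] - vm[idx])
  tc <- time[idx] + frac * (time[idx + 1] - time[idx])
  keep <- logical(length(tc))
  last <- -Inf
  for (i in seq_along(tc)) {
    if (tc[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- tc[i]
    }
  }
  tc[keep]
}

#' Group spikes into bursts
#'
#' Maximal runs of spikes whose consecutive inter-spike intervals are all
#' below `isi_gap`, kept if they contain at least `min_spikes` spikes.
#' Burst onset/offset are the first/last spike times.
#'
#' @param spikes strictly increasing spike times (s).
#' @param isi_gap maximal intra-burst inter-spike interval (s).
#' @param min_spikes minimal number of spikes per burst.
#' @return A data.frame with columns `onset`, `offset`, `n_spikes`.
#' @export
segment_bursts <- function(spikes, isi_gap = 0.3, min_spikes = 2) {
  if (!length(spikes)) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      n_spikes = integer(0)))
  }
  brk <- c(0, which(diff(spikes) >= isi_gap), length(spikes))
  on <- off <- numeric(0)
  ns <- integer(0)
  for (g in seq_len(length(brk) - 1)) {
    i0 <- brk[g] + 1
    i1 <- brk[g + 1]
    if (i1 - i0 + 1 >= min_spikes) {
      on <- c(on, spikes[i0])
      off <- c(off, spikes[i1])
      ns <- c(ns, i1 - i0 + 1L)
    }
  }
  data.frame(onset = on, offset = off, n_spikes = ns)
}

#' Group bursts into episodes
#'
#' Maximal runs of bursts separated by gaps (burst onset minus previous
#' burst offset) below `episode_gap`, kept if they contain at least
#' `min_bursts` bursts.  Episode onset is the first burst's onset (i.e. its
#' first spike) and episode offset the last burst's offset.
#'
#' @param bursts a data.frame from [segment_bursts()].
#' @param episode_gap maximal intra-episode inter-burst gap (s).
#' @param min_bursts minimal number of bursts per episode.
#' @return A data.frame with columns `onset`, `offset`, `n_bursts`,
#'   `first_burst`, `last_burst` (row indices into `bursts`).
#' @export
segment_episodes <- function(bursts, episode_gap = 4, min_bursts = 2) {
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      n_bursts = integer(0), first_burst = integer(0),
                      last_burst = integer(0))
  n <- nrow(bursts)
  if (!n) return(empty)
  gaps <- bursts$onset[-1] - bursts$offset[-n]
  brk <- c(0, which(gaps >= episode_gap), n)
  out <- empty
  for (g in seq_len(length(brk) - 1)) {
    i0 <- brk[g] + 1
    i1 <- brk[g + 1]
    if (i1 - i0 + 1 >= min_bursts) {
      out <- rbind(out, data.frame(
        onset = bursts$onset[i0], offset = bursts$offset[i1],
        n_bursts = i1 - i0 + 1L, first_burst = i0, last_burst = i1))
    }
  }
  out
}

.cv <- function(x) if (length(x) < 2 || mean(x) == 0) NA_real_ else
  stats::sd(x) / mean(x)

#' Rhythm metrics from segmented bursts and episodes
#'
#' Computes the full metric hierarchy: per-burst period (BP, onset to next
#' onset within an episode), duration (BD) and interburst interval (IBI);
#' per-episode period (EP, onset to next onset), duration (ED) and
#' interepisode interval (IEI, offset to next onset); summary means, SDs
#' and coefficients of variation; and the intra-episode burst-period
#' profile (first, second and last burst of each episode, plus
#' first-half/second-half means).
#'
#' With fewer than two episodes the EP/IEI statistics are `NA` (undefined),
#' not zero.
#'
#' @param bursts data.frame from [segment_bursts()].
#' @param episodes data.frame from [segment_episodes()].
#' @return An object of class `rhythm_metrics`: list with `bursts`,
#'   `episodes`, series `BP`, `BD`, `IBI`, `EP`, `ED`, `IEI`, a `summary`
#'   data.frame (mean, sd, cv, n per metric) and `intra_episode` (profile
#'   of BP/BD/IBI by position in the episode).
#' @export
rhythm_metrics <- function(bursts, episodes) {
  BP <- BD <- IBI <- numeric(0)
  first_bp <- second_bp <- last_bp <- numeric(0)
  bp_half1 <- bp_half2 <- numeric(0)
  plateau_bd <- plateau_ibi <- numeric(0)
  for (e in seq_len(nrow(episodes))) {
    i0 <- episodes$first_burst[e]
    i1 <- episodes$last_burst[e]
    b <- bursts[i0:i1, ]
    nb <- nrow(b)
    bd <- b$offset - b$onset
    BD <- c(BD, bd)
    if (nb >= 2) {
      bp <- diff(b$onset)
      ibi <- b$onset[-1] - b$offset[-nb]
      BP <- c(BP, bp)
      IBI <- c(IBI, ibi)
      first_bp <- c(first_bp, bp[1])
      if (length(bp) >= 2) second_bp <- c(second_bp, bp[2])
      last_bp <- c(last_bp, bp[length(bp)])
      half <- floor(length(bp) / 2)
      if (half >= 1) {
        bp_half1 <- c(bp_half1, mean(bp[seq_len(half)]))
        bp_half2 <- c(bp_half2, mean(bp[(half + 1):length(bp)]))
      }
      # plateau values: second half of the episode, where BP has levelled off
      sel <- seq(max(2, ceiling(nb / 2)), nb)
      plateau_bd <- c(plateau_bd, bd[sel])
      plateau_ibi <- c(plateau_ibi, ibi[pmin(sel, length(ibi))])
    }
  }
  ne <- nrow(episodes)
  EP <- if (ne >= 2) diff(episodes$onset) else numeric(0)
  ED <- episodes$offset - episodes$onset
  IEI <- if (ne >= 2) episodes$onset[-1] - episodes$offset[-ne] else
    numeric(0)
  series <- list(BP = BP, BD = BD, IBI = IBI, EP = EP, ED = ED, IEI = IEI)
  summ <- data.frame(
    metric = names(series),
    mean = vapply(series, function(x) if (length(x)) mean(x) else NA_real_,
                  0),
    sd = vapply(series, function(x) if (length(x) > 1) stats::sd(x) else
      NA_real_, 0),
    cv = vapply(series, .cv, 0),
    n = vapply(series, length, 0L))
  rownames(summ) <- NULL
  structure(c(series, list(
    bursts = bursts, episodes = episodes, summary = summ,
    intra_episode = list(
      first_bp = first_bp, second_bp = second_bp, last_bp = last_bp,
      bp_half1 = bp_half1, bp_half2 = bp_half2,
      plateau_bd = plateau_bd, plateau_ibi = plateau_ibi))),
    class = "rhythm_metrics")
}

#' @export
print.rhythm_metrics <- function(x, ...) {
  cat("rhythm_metrics:", nrow(x$bursts), "bursts in", nrow(x$episodes),
      "episodes\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Full spike -> burst -> episode analysis of a voltage channel
#'
#' @param time uniform time grid (s).
#' @param vm membrane potential samples (mV).
#' @param config an [analysis_config()].
#' @return A `rhythm_metrics` object (see [rhythm_metrics()]).
#' @export
analyze_vm <- function(time, vm, config = analysis_config()) {
  sp <- detect_spikes(time, vm, config$spike_threshold, config$refractory)
  b <- segment_bursts(sp, config$isi_gap, config$min_spikes)
  e <- segment_episodes(b, config$episode_gap, config$min_bursts)
  m <- rhythm_metrics(b, e)
  m$spikes <- sp
  m
}

#' Classify the activity regime of a trace
#'
#' Labels a post-transient voltage channel as `"silence"` (no spikes),
#' `"continuous"` (bursting with no inter-burst gap of at least
#' `episode_gap`), `"episodic"` (at least two episodes separated by such
#' gaps), or `"mixed"` otherwise.  Bistability is a property of a parameter
#' point (two initial conditions with different labels), not of one trace.
#'
#' @param trace an `hco_trace`, or a `rhythm_metrics` object.
#' @param channel voltage channel to classify (default first cell).
#' @param config an [analysis_config()].
#' @return Character label with attribute `metrics` (the
#'   `rhythm_metrics`).
#' @export
classify_regime <- function(trace, channel = NULL,
                            config = analysis_config()) {
  if (inherits(trace, "hco_trace")) {
    if (is.null(channel)) {
      channel <- if (trace$ncell == 2) "Vm.1" else "Vm"
    }
    m <- analyze_vm(trace$time, trace_channel(trace, channel), config)
  } else if (inherits(trace, "rhythm_metrics")) {
    m <- trace
  } else stop("trace must be an hco_trace or rhythm_metrics object",
              call. = FALSE)
  nb <- nrow(m$bursts)
  ne <- nrow(m$episodes)
  label <- if (length(m$spikes) == 0 || nb == 0) {
    "silence"
  } else {
    gaps <- if (nb >= 2) m$bursts$onset[-1] - m$bursts$offset[-nb] else
      numeric(0)
    if (nb >= 2 && all(gaps < config$episode_gap)) {
      "continuous"
    } else if (ne >= 2 && any(m$IEI >= config$episode_gap)) {
      "episodic"
    } else "mixed"
  }
  attr(label, "metrics") <- m
  label
}

#' Envelope-based episode detection for DC neurogram signals
#'
#' Implements the detection pipeline used for experimental-style signals:
#' linear detrend, zero-phase band-pass (0.01-1 Hz, 2nd-order Butterworth),
#' rectification and Gaussian-weighted moving-average smoothing, then
#' hysteresis thresholding of the envelope (on at `on_frac`, off at
#' `off_frac` of the robust envelope amplitude, median to 95th percentile).
#'
#' @param signal DC signal samples.
#' @param fs sampling rate (Hz), at least 2 Hz.
#' @param gauss_sd Gaussian smoothing width (s).
#' @param on_frac,off_frac hysteresis thresholds as fractions of the robust
#'   envelope amplitude.
#' @return List with `envelope` (same length as `signal`), `onsets`,
#'   `offsets` (s), and `episodes` (data.frame with onset/offset), suitable
#'   for [rhythm_metrics()]-style episode statistics.
#' @export
neurogram_envelope <- function(signal, fs, gauss_sd = 0.5,
                               on_frac = 0.5, off_frac = 0.2) {
  stopifnot(fs >= 2)
  n <- length(signal)
  if (n / fs < 3 / 0.01) {
    warning("record shorter than 3x the 0.01 Hz low-cutoff period; ",
            "low-frequency content unreliable")
  }
  t <- seq_len(n) / fs
  detr <- stats::residuals(stats::lm(signal ~ t))
  # reflective padding suppresses filter edge transients
  pad <- min(n - 1, round(30 * fs))
  padded <- c(rev(detr[seq_len(pad) + 1]), detr,
              rev(detr[(n - pad):(n - 1)]))
  bf <- signal::butter(2, c(0.01, 1) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, padded)[(pad + 1):(pad + n)]
  rect <- abs(bp)
  # Gaussian-weighted moving average
  half <- max(1L, round(3 * gauss_sd * fs))
  k <- stats::dnorm(seq(-half, half) / fs, sd = gauss_sd)
  k <- k / sum(k)
  env <- stats::filter(c(rep(rect[1], half), rect, rep(rect[n], half)),
                       k, sides = 2)
  env <- as.numeric(env[(half + 1):(half + n)])
  amp <- stats::quantile(env, 0.95, names = FALSE) - stats::median(env)
  base <- stats::median(env)
  if (amp <= 1e-9 * max(1, diff(range(signal)))) {
    return(list(envelope = env, onsets = numeric(0),
                offsets = numeric(0),
                episodes = data.frame(onset = numeric(0),
                                      offset = numeric(0))))
  }
  hi <- base + on_frac * amp
  lo <- base + off_frac * amp
  on <- off <- numeric(0)
  inside <- FALSE
  for (i in seq_len(n)) {
    if (!inside && env[i] >= hi) {
      inside <- TRUE
      on <- c(on, t[i])
    } else if (inside && env[i] <= lo) {
      inside <- FALSE
      off <- c(off, t[i])
    }
  }
  if (inside) on <- on[-length(on)]      # drop unterminated episode
  eps <- data.frame(onset = on, offset = off)
  list(envelope = env, onsets = on, offsets = off, episodes = eps)
}
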