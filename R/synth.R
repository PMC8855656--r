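#' Specification for a synthetic episodic trace
#'
#' Describes a ground-truth episodic signal used to validate the
#' spike/burst/episode detectors and the neurogram-envelope pipeline:
#' square-envelope episodes of duration `ED` repeating with period `EP`,
#' each carrying a regular train of bursts of spike-like events, plus
#' optional slow linear drift and Gaussian noise (emulating DC
#' neurograms).
#'
#' @param mode `"vm"` for a membrane-potential-like trace (baseline
#'   -60 mV, spikes overshooting 0 mV) or `"neurogram"` for a DC
#'   neurogram-like trace (zero baseline, burst-modulated envelope).
#' @param EP episode period (s).
#' @param ED episode duration (s), < EP.
#' @param burst_rate intra-episode burst rate (Hz).
#' @param spikes_per_burst spike events per burst.
#' @param spike_isi intra-burst inter-spike interval (s).
#' @param spike_width triangular spike half-width (s).
#' @param spike_amp spike amplitude above baseline (mV or a.u.).
#' @param baseline baseline level (mV or a.u.).
#' @param noise_sd Gaussian noise standard deviation.
#' @param drift_slope linear drift (units/s).
#' @param duration total trace duration (s).
#' @param sample_dt sampling interval (s).
#' @param seed integer seed; generation is seed-deterministic.
#' @return A list of class `synthetic_trace_spec`.
#' @export
synthetic_trace_spec <- function(mode = c("vm", "neurogram"),
                                 EP = 50, ED = 20,
                                 burst_rate = 1, spikes_per_burst = 5,
                                 spike_isi = 0.02, spike_width = 0.004,
                                 spike_amp = 70, baseline = -60,
                                 noise_sd = 0, drift_slope = 0,
                                 duration = 200, sample_dt = 5e-4,
                                 seed = 1) {
  mode <- match.arg(mode)
  stopifnot(ED < EP, ED > 0, EP > 0, duration > 0, sample_dt > 0,
            burst_rate > 0, spikes_per_burst >= 1)
  if (duration < 1 + ED) {
    stop("duration must be at least ED + 1 s (episodes start at t = 1)",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "synthetic_trace_spec")
}

#' Generate a synthetic trace with ground-truth annotations
#'
#' Builds the signal described by a [synthetic_trace_spec()] and returns
#' it together with the exact spike, burst and episode times used to
#' construct it, so detector output can be compared against truth.
#' All randomness (noise) is controlled by the spec's seed.
#'
#' @param spec a [synthetic_trace_spec()].
#' @return List of class `synthetic_trace` with `time`, `signal`,
#'   `truth` (list: `spikes`, `bursts` data.frame, `episodes` data.frame),
#'   and `spec`.
#' @export
generate_synthetic_trace <- function(spec = synthetic_trace_spec()) {
  stopifnot(inherits(spec, "synthetic_trace_spec"))
  set.seed(spec$seed)
  n <- floor(spec$duration / spec$sample_dt) + 1
  t <- seq(0, by = spec$sample_dt, length.out = n)
  sig <- rep(if (spec$mode == "vm") spec$baseline else 0, n)

  ep_onsets <- seq(1, spec$duration - spec$ED, by = spec$EP)
  spikes <- numeric(0)
  bursts <- NULL
  burst_period <- 1 / spec$burst_rate
  train_len <- (spec$spikes_per_burst - 1) * spec$spike_isi
  for (on in ep_onsets) {
    b_onsets <- seq(on, on + spec$ED - train_len, by = burst_period)
    for (bo in b_onsets) {
      sp <- bo + (seq_len(spec$spikes_per_burst) - 1) * spec$spike_isi
      spikes <- c(spikes, sp)
      bursts <- rbind(bursts, data.frame(onset = sp[1],
                                         offset = sp[length(sp)],
                                         n_spikes = length(sp)))
    }
  }
  episodes <- data.frame(onset = ep_onsets,
                         offset = ep_onsets +
                           (floor((spec$ED - train_len) / burst_period)) *
                           burst_period + train_len)

  if (spec$mode == "vm") {
    # triangular spikes with analytically known threshold crossings
    half <- spec$spike_width
    for (sp in spikes) {
      sel <- which(t >= sp - half & t <= sp + half)
      tri <- 1 - abs(t[sel] - sp) / half
      sig[sel] <- pmax(sig[sel], spec$baseline + spec$spike_amp * tri)
    }
  } else {
    # neurogram: burst-rate-modulated oscillation inside episodes
    for (e in seq_len(nrow(episodes))) {
      sel <- t >= episodes$onset[e] & t <= episodes$offset[e]
      sig[sel] <- sig[sel] + spec$spike_amp *
        abs(sin(pi * spec$burst_rate * (t[sel] - episodes$onset[e])))
    }
  }
  sig <- sig + spec$drift_slope * t
  if (spec$noise_sd > 0) sig <- sig + stats::rnorm(n, 0, spec$noise_sd)

  structure(list(time = t, signal = sig,
                 truth = list(spikes = spikes, bursts = bursts,
                              episodes = episodes),
                 spec = spec),
            class = "synthetic_trace")
}

#' @export
print.synthetic_trace <- function(x, ...) {
  cat(sprintf(
    "synthetic_trace (%s): %.4g s at dt = %.3g s; %d spikes, %d bursts, %d episodes\n",
    x$spec$mode, x$spec$duration, x$spec$sample_dt,
    length(x$truth$spikes), nrow(x$truth$bursts), nrow(x$truth$episodes)))
  invisible(x)
}
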