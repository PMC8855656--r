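test_that("spike detection finds threshold crossings and honours the refractory period", {
  # constant trace: nothing to detect
  t <- seq(0, 10, by = 1e-3)
  expect_length(detect_spikes(t, rep(-60, length(t))), 0)
  # synthetic triangular spikes at 10 Hz with known crossing times
  syn <- generate_synthetic_trace(synthetic_trace_spec(
    EP = 10, ED = 2, burst_rate = 10, spikes_per_burst = 1,
    duration = 4, sample_dt = 1e-4))
  sp <- detect_spikes(syn$time, syn$signal, -20, 0.003)
  truth <- syn$truth$spikes
  # upward crossing of -20 mV on a triangular spike of amplitude 70 from
  # -60 happens at 4/7 of the rise
  expected <- truth - syn$spec$spike_width * (1 - 40 / 70)
  expect_equal(length(sp), length(truth))
  expect_lt(max(abs(sp - expected)), 2e-4)
  # threshold above the peak: nothing
  expect_length(detect_spikes(syn$time, syn$signal, 50, 0.003), 0)
  # refractory swallowing: with a huge refractory only one spike remains
  expect_length(detect_spikes(syn$time, syn$signal, -20, 10), 1)
  expect_error(detect_spikes(c(0, 0.1, 0.3), c(1, 2, 3)), "uniform")
})

test_that("burst segmentation groups spikes by inter-spike gap with a minimum count", {
  expect_equal(nrow(segment_bursts(numeric(0))), 0)
  # 3 groups of 5 spikes at 0.05 s ISI, onsets 0.6 s apart:
  # BD = 0.2 s and IBI = 0.4 s by construction
  sp <- as.vector(sapply(c(0, 0.6, 1.2), function(o) o + 0:4 * 0.05))
  b <- segment_bursts(sp, isi_gap = 0.3, min_spikes = 2)
  expect_equal(nrow(b), 3)
  expect_equal(b$offset - b$onset, rep(0.2, 3))
  expect_equal(b$onset[-1] - b$offset[-3], rep(0.4, 2))
  expect_equal(b$n_spikes, rep(5L, 3))
  # isolated spikes dropped when min_spikes = 2
  b2 <- segment_bursts(c(sp, 5), isi_gap = 0.3, min_spikes = 2)
  expect_equal(nrow(b2), 3)
})

test_that("episode segmentation and metrics reproduce a constructed arithmetic fixture", {
  # episodes starting at 0, 50, 100 s, each 20 s of bursts 1 s apart
  sp <- as.vector(sapply(c(0, 50, 100), function(o)
    o + rep(0:19, each = 2) + c(0, 0.1)))
  b <- segment_bursts(sort(sp), isi_gap = 0.3, min_spikes = 2)
  e <- segment_episodes(b, episode_gap = 4, min_bursts = 2)
  expect_equal(nrow(e), 3)
  m <- rhythm_metrics(b, e)
  s <- m$summary
  expect_equal(s[s$metric == "EP", "mean"], 50)
  expect_equal(s[s$metric == "ED", "mean"], 19.1)
  expect_equal(s[s$metric == "IEI", "mean"], 30.9)
  expect_equal(s[s$metric == "EP", "cv"], 0)
  # reconstruction identity: EP_j = ED_j + IEI_j
  expect_equal(m$EP, m$ED[-length(m$ED)] + m$IEI)
  # within episodes: BP = BD + IBI
  expect_equal(m$BP, rep(1, length(m$BP)))
  # single cluster: one episode, empty EP/IEI flagged undefined not zero
  e1 <- segment_episodes(b[1:20, ], episode_gap = 4, min_bursts = 2)
  m1 <- rhythm_metrics(b[1:20, ], e1)
  expect_true(is.na(m1$summary[m1$summary$metric == "EP", "mean"]))
  expect_length(m1$IEI, 0)
})

test_that("regime classification distinguishes silence, continuous and episodic traces", {
  t <- seq(0, 300, by = 1e-3)
  cfg <- analysis_config()
  sil <- analyze_vm(t, rep(-60, length(t)), cfg)
  expect_equal(as.character(classify_regime(sil, config = cfg)), "silence")
  # continuous: bursts with sub-second gaps over the whole record
  syn_c <- generate_synthetic_trace(synthetic_trace_spec(
    EP = 298, ED = 295, burst_rate = 1, duration = 300))
  mc <- analyze_vm(syn_c$time, syn_c$signal, cfg)
  expect_equal(as.character(classify_regime(mc, config = cfg)),
               "continuous")
  # episodic: 20 s episodes, 30 s gaps
  syn_e <- generate_synthetic_trace(synthetic_trace_spec(
    EP = 50, ED = 20, duration = 300))
  me <- analyze_vm(syn_e$time, syn_e$signal, cfg)
  expect_equal(as.character(classify_regime(me, config = cfg)), "episodic")
})

test_that("noise-free detector recovery is exact across generator settings", {
  # property over EP, duty cycle and burst rate under a fixed seed grid
  cases <- expand.grid(EP = c(25, 60, 110), duty = c(0.25, 0.6),
                       rate = c(0.5, 2))
  for (i in seq_len(nrow(cases))) {
    spec <- synthetic_trace_spec(
      EP = cases$EP[i], ED = cases$EP[i] * cases$duty[i],
      burst_rate = cases$rate[i],
      spikes_per_burst = 4, spike_isi = 0.02,
      duration = 3.2 * cases$EP[i], sample_dt = 5e-4, seed = i)
    syn <- generate_synthetic_trace(spec)
    m <- analyze_vm(syn$time, syn$signal,
                    analysis_config(isi_gap = 0.25,
                                    episode_gap = 1 / cases$rate[i] + 2))
    truth <- syn$truth$episodes
    expect_equal(nrow(m$episodes), nrow(truth))
    # onsets anchored at first spike of first burst; crossing offset only
    expect_lt(max(abs(m$episodes$onset - truth$onset)), 5e-3)
    expect_lt(max(abs(m$episodes$offset - truth$offset)), 5e-3)
  }
})

test_that("classification is stable across episode-gap choices for model traces", {
  m <- canonical_metrics()
  b <- m$bursts
  # the gap spectrum separates intra-episode interburst intervals from
  # interepisode intervals over a window around the default 4 s
  for (gap in c(3, 4)) {
    e <- segment_episodes(b, episode_gap = gap, min_bursts = 2)
    mm <- rhythm_metrics(b, e)
    mm$spikes <- m$spikes
    expect_equal(as.character(
      classify_regime(mm, config = analysis_config(episode_gap = gap))),
      "episodic")
  }
})

test_that("neurogram envelope kills trends, ignores constants and recovers episode timing", {
  fs <- 50
  t <- seq(1 / fs, 400, by = 1 / fs)
  ramp <- suppressWarnings(neurogram_envelope(0.3 * t, fs))
  expect_lt(max(abs(ramp$envelope)), 1)
  expect_length(ramp$onsets, 0)
  const <- suppressWarnings(neurogram_envelope(rep(3, length(t)), fs))
  expect_length(const$onsets, 0)
  syn <- generate_synthetic_trace(synthetic_trace_spec(
    mode = "neurogram", EP = 50, ED = 20, burst_rate = 5,
    spike_amp = 1, baseline = 0, noise_sd = 0.1, drift_slope = 0.002,
    duration = 400, sample_dt = 1 / fs, seed = 7))
  env <- neurogram_envelope(syn$signal, fs)
  truth <- syn$truth$episodes
  # ignore detections in the filter-unreliable leading margin
  keep <- env$onsets > 30
  on <- env$onsets[keep]
  off <- env$offsets[keep]
  tr_keep <- truth[truth$onset > 30, ]
  expect_equal(length(on), nrow(tr_keep))
  expect_lt(mean(abs(diff(on) - 50)) / 50, 0.02)     # EP within 2%
  expect_lt(mean(abs((off - on) - 20)) / 20, 0.10)   # ED within 10%
})
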