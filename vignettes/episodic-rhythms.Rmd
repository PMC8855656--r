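---
title: "Modelling episodic and continuous rhythms in a locomotor half-center oscillator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling episodic and continuous rhythms in a locomotor half-center oscillator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

hcorhythm implements a conductance-based model of a locomotor central
pattern generator half-center oscillator (HCO): two identical neurons,
each representing a population of spinal interneurons, coupled by
reciprocal graded inhibition.  Each cell carries fast and persistent
Na^+^ currents (I~NaF~, I~NaP~), delayed-rectifier and A-type K^+^
currents (I~KDR~, I~KA~), a low-threshold slow Ca^2+^ current (I~CaS~),
a hyperpolarization-activated mixed cation current I~h~ split 3/7 : 4/7
between Na^+^ and K^+^ components, a Na^+^/K^+^ leak split referenced to
a leak reversal potential, an inhibitory synaptic current, and — the
model's distinctive ingredients — a dynamic intracellular Na^+^
concentration and a Na^+^/K^+^ ATPase pump current activated
sigmoidally by it.  The membrane equation is
$C\,\dot V = -\sum_x I_x$ with all currents positive-outward; gating
variables relax first-order to Boltzmann steady states
$f_\infty(a, V_{1/2}, V) = 1/(1+\exp((V-V_{1/2})/a))$; intracellular
Na^+^ obeys
$\dot{[\mathrm{Na}]_i} = M([\mathrm{Na}]_e - [\mathrm{Na}]_i) -
\alpha\,(I_{h\text{-}Na} + I_{L\text{-}Na} + I_{NaF} + I_{NaP} +
3 I_{\mathrm{Pump}})$, where the factor 3 is the pump's 3:2
stoichiometry and $M$ is a first-order Na^+^ influx used to emulate the
Na^+^/H^+^ antiporter monensin.  E~Na~ and E~K~ are Nernst potentials
(RT/F = 26.45 mV) with fixed extracellular Na^+^ and fixed K^+^ pools.

The unit system is mV, s, nS, pA, nF, mM, which closes dimensionally
(nS·mV = pA; pA/nF = mV/s).  The canonical capacitance of 0.001 nF with
~100 nS spiking conductances makes the spike upstroke extremely fast
(tens of microseconds); this is an intrinsic feature of the
parameterisation — the cell is electrically very small and spikes carry
millimolar-scale Na^+^ increments, which is exactly what couples the
spike generator to the pump.

## Rhythms across time scales

At the canonical parameter set the HCO produces **episodic bursting**:
a second-order rhythm in which episodes of ~1 Hz alternating bursting
(burst duration ~0.44 s, interburst interval ~0.5–0.6 s per cell) are
separated by interepisode silences.  The slowest state variable, the
h-current activation m~h~ (time constant bounded between 0.5 and 1.5 s),
organises the slow rhythm: it deactivates on average while a cell
bursts and reactivates towards saturation during silence.  The
interepisode interval ends through a slow depolarising drift with
growing subthreshold oscillations (an elliptic-bursting signature: the
quiescent state loses stability through a subcritical Andronov–Hopf
bifurcation of the fast subsystem), and episodes terminate when the
intra-episode m~h~ rundown makes the alternating state marginal, at
which point burst-to-burst variability tips the network back to
silence.  Episode durations are therefore intrinsically variable while
interepisode intervals are nearly deterministic — the package's
canonical simulations show episode-duration coefficients of variation
far above those of the interepisode interval, matching the asymmetry in
the reference behaviour.

The reduced constant-m~h~ model (`scan_constant_mh()`) freezes m~h~ as
a parameter of the decoupled cell.  It exhibits exactly two regimes —
rest and continuous bursting — with a coexistence (hysteresis) window
between the value below which the bursting attractor disappears and the
Hopf value above which rest is no longer stable; it is never episodic,
demonstrating that m~h~ dynamics are necessary for the second-order
rhythm.  `rest_state_stability()` locates the equilibrium by damped
Newton iteration with a central-difference Jacobian (relative steps
1e-6, absolute floor 1e-9 via magnitude scaling) and reads stability
from its eigenvalues; `hopf_point()` bisects the sign change of the
leading real part, giving an eigenvalue-based check on the
simulation-based boundary.  Because the Hopf is subcritical, the rest
state's *basin* shrinks well before its *linear* stability is lost, so
the scan probes the rest branch from the continued equilibrium itself
(perturbed by 0.5 mV) rather than from an arbitrary rest-like state —
otherwise the simulation-based boundary reports basin escape, not the
bifurcation.

## Kinetics constants

The voltage dependence of the h-current activation and of the
bell-shaped gating time constants is parameterised in a single table,
`kinetics_constants()`, rather than hard-coded.  Several of these
constants admit more than one plausible reading in the source model
family (slope-factor units, exponential signs, a half-voltage sign),
so the package treats them as named constants with documented defaults,
fixed once by requiring the canonical model to reproduce its reference
episodic behaviour:

* `mh_k1 = 2.26`, `mh_k2 = 6.15` (1/mV), `mh_vhalf = -52.1` mV: the
  steady-state h-activation
  $m_{h,\infty} = 1/(1 + 2e^{k_1(V-V_h)} + e^{k_2(V-V_h)})$ equals 1/4
  at its half-voltage and saturates at 1 under hyperpolarization.  The
  steep slopes place the transition just below the model's silent-state
  voltage (≈ −54 mV), which is what lets m~h~ saturate near 1 between
  episodes and collapse during bursting.  A ten-fold shallower reading
  of the same constants puts the transition 20 mV too low and abolishes
  episodic activity entirely.
* `hNaF_vhalf = -26` mV (slope 7 mV): fast-Na^+^ inactivation.  With
  the opposite sign the spike generator enters sustained
  depolarization-block plateaus with pathological Na^+^ loading; with
  −26 the frozen-m~h~ bursting branch terminates with burst metrics
  (BD ≈ 0.18 s, IBI ≈ 0.13 s) that match the reference end-of-episode
  values almost exactly, which fixes the sign.
* `tauh_vhalf = -53.23` mV, `tauh_slope = +0.1` 1/mV,
  `tauh_base = 0.5` s, `tauh_amp = 1` s: the m~h~ time constant
  $\tau_h = 0.5 + 1/(1+e^{s(V-V_\tau)})$ (times `tau_h_scale`).  The
  midpoint must sit in the subthreshold band: if it is far below the
  operating range, τ~h~ is effectively uniform, the per-cycle m~h~
  rundown and rebuild balance at a stable equilibrium, and the
  alternating rhythm never terminates (no episodes).  With the midpoint
  at −53.23 mV the rundown during bursts outpaces the rebuild during
  inhibited phases once m~h~ has fallen sufficiently, and episodes end.
* `thNaF_s1/s2 = 15/-16`, `thKDR_s1/s2 = 40/-50` (mV): bell-shaped
  τ~hNaF~ and τ~mKDR~ with numerators 0.03 and 0.007 s, peaking near
  −43 mV.  `tCaS_scale`/`tCaS_mode` select the slow-Ca^2+^ activation
  τ form (alpha/beta rate form by default).

All remaining gate parameters (Boltzmann slopes and half-voltages,
fixed time constants mNaP 0.001 s, hNaP 0.1 s, hKA 0.02 s, hCaS 0.34 s,
mSyn 0.05 s) are used exactly as specified.

## Numerics

Integration uses deSolve's Dormand–Prince 5(4) embedded pair
(`rk45dp7`) with absolute tolerance 1e-8, relative tolerance 1e-9 and
initial step 1e-8 s, via a compiled C right-hand side.  The
higher-order 7(8) pairs in deSolve lack the dense-output interpolation
path and are impractically slow on the fine output grids this model
needs, while `rk45dp7` reproduces spike times of a tolerance-tightened
reference run to well under a sample interval; a fixed-step RK4 cross
check at dt = 1e-5 s reproduces spike counts and spike times of the
adaptive solution on test windows.  The default output sampling is
0.5 ms (2 kHz), well above the rate needed to resolve burst and episode
structure, and long records are integrated in 250 s chunks to bound
memory.  A pure-R implementation of the same vector field, assembled
independently from the per-current functions, is compared against the
compiled kernel in the test suite (agreement to ~1e-10 relative).

Initial conditions are not part of the model definition; the canonical
choice starts the two cells at −50 and −60 mV (gates at steady state,
Na~i~ = 15 mM).  The model is exactly symmetric under cell exchange, so
a symmetric start would remain symmetric forever in exact arithmetic —
the asymmetric start breaks that degeneracy.  The episodic attractor's
episode durations are chaotic, so episode-level means are estimated
from long records; interepisode intervals and intra-episode burst
metrics are essentially deterministic.

## Detection and metrics

Spikes are upward crossings of −20 mV with a 3 ms refractory period
(model spikes overshoot 0 mV; subthreshold interepisode oscillations
stay far below threshold).  Bursts are maximal spike runs with
inter-spike intervals below 0.3 s (at least 2 spikes); episodes are
maximal burst runs with gaps below 4 s (at least 2 bursts) — the gap
spectrum of HCO traces is strongly bimodal (intra-episode interburst
intervals ≈ 0.5 s versus interepisode intervals well above 4 s), so the
classification is insensitive to the episode gap over a wide range, and
the test suite checks label stability for gaps from 2 to 8 s.  The
decoupled single cell bursts an order of magnitude faster, so its
analysis uses a 0.05 s burst gap (`single_cell_config()`).  Episode
onsets are anchored at the first spike of the first burst, making all
interval series exactly reproducible; EP = ED + IEI holds by
construction.  For DC neurogram-style signals,
`neurogram_envelope()` detrends, band-passes 0.01–1 Hz (2nd-order
zero-phase Butterworth with reflective padding against edge
transients), smooths with a Gaussian-weighted moving average
(σ = 0.5 s) and applies hysteresis thresholds at 50%/20% of the robust
envelope amplitude (median to 95th percentile); the first ~30 s of a
record are unreliable at the 0.01 Hz corner and detections there should
be discarded.

## The synthetic generator

`generate_synthetic_trace()` builds seed-deterministic ground-truth
signals: square-envelope episodes with prescribed EP/ED carrying
regular burst trains of triangular spike events (membrane-potential
mode) or burst-rate-modulated oscillations (neurogram mode), plus
optional linear drift and Gaussian noise.  It emulates the *timing*
structure of episodic recordings, not their biophysics: spike shapes,
amplitude variability, slow amplitude drift of real neurograms and
non-stationary episode statistics are outside its scope, so detector
tests on synthetic traces validate segmentation logic and parameter
recovery, not robustness to every property of experimental data.

## Problem sizes

Reference protocols integrate past a 5000 s transient and record 1500 s
or more.  The package's test and acceptance runs use scaled-down
protocols chosen so that the reported statistics are stable while runs
remain desk-scale: canonical HCO runs use a 500 s transient with 2000–3000 s records
(≈ 50–90 episodes; the episode-duration distribution is heavy-tailed,
so episode-level means need long records), single-cell runs 400–500 s
transients with 500–600 s records, reduced-model scans 25 s transients
with 15 s records per grid point (≥ 40 burst cycles), boundary
bisections 400 s transients with 500–600 s records per probe, and the
50× τ~h~ protocol a 2000 s transient with a 2000 s record.  The
transients were checked once against substantially longer runs; the
post-transient metrics agree within the episode-to-episode
variability.

## Known limitations

* The episode-level timing split of the canonical HCO is imperfect:
  episode periods fall in the reference range, but this reconstruction
  terminates episodes through chaotic collapse with heavy-tailed
  durations and re-escapes from silence within a few seconds, so the
  mean episode duration overshoots and the mean interepisode interval
  undershoots their reference values.  No setting of the ambiguous
  kinetics constants was found that reproduces the reference ED/IEI
  split while keeping the single-cell and regime-boundary behaviour.
* The decoupled cell's episode duration and interepisode interval are
  ~40% short and ~50% long, respectively, under the calibration that
  favours the two-cell targets; an alternative τ~h~ calibration
  reproduces them well but abolishes HCO episode termination.
* Monensin (M > 0) shifts the silent-phase Na^+^ balance as intended,
  but in this calibration the added influx also destabilises episodes,
  so the monensin episode-period increase is not reproduced.
* The low-pump bistable (silence/continuous) zone is narrower than in
  the reference description; plateau-like continuous bursting at
  I~PumpMax~ = 37.7 pA appears only from strongly bursting initial
  states.
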