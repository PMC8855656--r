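# hcorhythm

Conductance-based modelling of **episodic rhythmicity** in the neonatal
mouse locomotor central pattern generator, built around a half-center
oscillator (HCO): two identical, mutually inhibitory Hodgkin–Huxley
neurons with a dynamic intracellular Na⁺ concentration, an
activity-dependent Na⁺/K⁺ ATPase pump current, and a
hyperpolarization-activated mixed-cation h-current.

Developing spinal locomotor networks produce *episodes* of rhythmic
bursting separated by long quiescent intervals — a rhythm of rhythms.
This package implements a biophysical explanation of that pattern and
the tools to analyse it:

* **Model core** — the full two-cell vector field (fast/persistent Na⁺,
  delayed-rectifier and A-type K⁺, slow Ca²⁺, split Na⁺/K⁺ leak and
  h-current (3/7 Na⁺ : 4/7 K⁺), graded inhibition, Nernst reversals,
  pump current `IPump = IPumpMax / (1 + exp((25 − [Na]ᵢ)/3)) / (1 +
  exp(6 − [K]ₑ))`, and Na⁺ balance
  `d[Na]ᵢ/dt = M([Na]ₑ − [Na]ᵢ) − α(I_hNa + I_LNa + I_NaF + I_NaP +
  3·I_Pump)`), compiled in C and integrated with adaptive embedded
  Runge–Kutta methods (deSolve).
* **Reduced models** — the decoupled single cell, the τ_h-scaled cell,
  and the frozen-m_h model with a numerical bifurcation scan and
  eigenvalue-based equilibrium stability (`scan_constant_mh()`,
  `rest_state_stability()`, `hopf_point()`): episodic bursting is
  *elliptic* — organised around a subcritical Andronov–Hopf bifurcation
  of the fast subsystem, with the slow h-current activation m_h carrying
  the system across a hysteresis loop of rest and continuous bursting.
* **Rhythm analysis** — spike → burst → episode segmentation with the
  full metric hierarchy (burst period/duration/interburst interval;
  episode period/duration/interepisode interval; CVs; intra-episode
  burst-period profiles), regime classification (silence / episodic /
  continuous / bistable via two-IC probing), and an envelope pipeline
  for DC neurogram signals (detrend, 0.01–1 Hz zero-phase band-pass,
  Gaussian smoothing, hysteresis thresholds).
* **Experiments** — scripted parameter sweeps (ḡ_h, I_PumpMax, monensin
  rate constant M, τ_h scale), regime-boundary bisection, bistability
  probes, and full-model-on-reduced-diagram overlays.
* **Synthetic data** — a seed-deterministic generator of ground-truth
  episodic traces (spike trains or DC neurograms) for detector
  validation.

For whom: computational neuroscientists studying central pattern
generators, slow–fast bursting, or Na⁺/pump dynamics, and
electrophysiologists who want the accompanying episode-detection
pipeline for DC neurogram recordings.

## A worked example

Simulate the canonical HCO past its transient, then segment and
summarise the rhythm:

```r
library(hcorhythm)

p  <- hco_parameters()                      # canonical parameter set
tr <- integrate_hco(p, transient = 500, record = 4000)
label <- classify_regime(tr, "Vm.1")
m  <- attr(label, "metrics")
label
#> [1] "episodic"
print(m)
#> rhythm_metrics: 2120 bursts in 80 episodes
#>   metric    mean       sd      cv    n
#> 1     BP  1.7809   1.1860 0.66595 2040
#> 2     BD  0.4389   0.1359 0.30970 2120
#> 3    IBI  1.3413   1.1838 0.88257 2040
#> 4     EP 48.0100 127.3533 2.65264   79
#> 5     ED 45.8334 127.8444 2.78933   80
#> 6    IEI  4.1848   0.1612 0.03853   79
```

The cells burst in alternation within episodes (burst duration
≈ 0.44 s), the mean episode period is ≈ 48 s, and the interepisode
interval is nearly deterministic (CV ≈ 0.04) while episode durations
vary strongly — the signature of episodes that terminate through
burst-to-burst variability of a marginal alternating state.

Freeze the slow variable to see the fast subsystem's skeleton:

```r
sc <- scan_constant_mh(p, grid = seq(0.72, 1, by = 0.01),
                       transient = 25, record = 15)
print(sc)
#> Reduced constant-m_h bifurcation scan over [ 0.72 , 1 ]
#>
#>   bursting coexistent       rest
#>          2         20          7
#> bursting attractor disappears below m_h ~ 0.790
#> rest state loses stability above  m_h ~ 0.980
```

Between those two boundaries rest and continuous bursting coexist; the
full model's m_h range straddles both, which is what makes episodic
cycling possible (and why it disappears when m_h is frozen).

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/hco.R simulate --transient 500 --record 2000 --out trace.csv
Rscript inst/cli/hco.R analyze  --trace trace.csv --mode vm --out metrics.csv
Rscript inst/cli/hco.R sweep    --param gh --grid 0.32:0.37:0.01 --out sweep.csv
Rscript inst/cli/hco.R boundary --param gh --lo 0.34 --hi 0.40 \
        --from episodic --to continuous --res 0.004
Rscript inst/cli/hco.R bifurcate --grid 0.72:1:0.01 --out diagram.csv
Rscript inst/cli/hco.R synth    --ep 50 --ed 20 --duration 200 --out synthetic.csv
```

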