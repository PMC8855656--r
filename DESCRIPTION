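Package: hcorhythm
Title: Half-Center Oscillator Model of Episodic Locomotor Rhythms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conductance-based model of a locomotor central pattern
    generator half-center oscillator (HCO): two mutually inhibitory
    Hodgkin-Huxley neurons with dynamic intracellular sodium, an
    activity-dependent Na+/K+ ATPase pump current and a
    hyperpolarization-activated (h-) current.  Provides a compiled
    vector field integrated with high-order embedded Runge-Kutta
    methods (deSolve), reduced single-cell and frozen-m_h models with
    numerical bifurcation and equilibrium-stability analysis,
    spike/burst/episode segmentation with rhythm metrics (burst and
    episode periods, durations, intervals and their coefficients of
    variation), regime classification (silence, episodic, continuous,
    bistable), scripted parameter-sweep and boundary-bisection
    experiments, a neurogram-envelope pipeline for DC extracellular
    signals, and a seed-deterministic synthetic trace generator for
    detector validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: deSolve, signal, stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
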