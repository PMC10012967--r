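Package: duplexsep
Title: Two-Layer Adaptive Phase-Oscillator Model of Sepsis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a functional two-layer
    (parenchyma / immune) network model of sepsis built from adaptively
    coupled phase oscillators.  Cytokine signalling is represented by slow
    adaptive coupling weights within each layer and a fixed bidirectional
    interlayer coupling.  The package integrates the coupled phase/weight
    differential equations with a compiled right-hand side, generates the
    perturbed initial conditions that model a systemic immune activation,
    computes synchronization measures (mean phase velocities, the second
    Kuramoto-Daido order parameter, frequency-cluster detection, interlayer
    phase locking), classifies asymptotic states as healthy, vulnerable or
    pathological, runs seeded ensembles over parameter grids to produce
    regime maps, and evaluates the analytic reduced model of the fully
    synchronized state (interlayer phase lag, existence bound, common
    frequency).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
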