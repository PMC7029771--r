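Package: kinbind
Title: Simulation and Global Fitting of Competition Association Binding Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing kinetic probe
    competition assays (kPCA) and equilibrium probe competition assays (ePCA).
    Implements the Motulsky-Mahan "kinetics of competitive binding" model in
    raw-signal, normalised and signal-drift-corrected forms, pseudo-first-order
    tracer association and association-then-dissociation models, mass-action
    ODE mechanisms (reversible 1:1, irreversible, induced fit), a Monte Carlo
    assay simulator with configurable noise and injected systematic errors,
    deterministic multi-start global nonlinear least-squares fitters with
    ill-determinedness diagnostics, and precision/accuracy metrics
    (CV, relative error, Z'-factor, Bland-Altman log differences).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
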