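Package: cdk1diauxia
Title: Diauxic CDK1/Cyclin B Activation Dynamics under CDC6 Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a mass-action model of mitotic entry in which the CDC6
    protein sequesters inactive CDK1/cyclin B complexes and thereby delays the
    CDK1-CDC25 positive feedback loop, producing two-phase ("diauxic")
    activation curves. Provides the dimensional, non-dimensional and reduced
    three-variable right-hand sides with a Hill-type switch on the CDC6
    binding rate, a fixed-step classical Runge-Kutta integrator with
    steady-state stopping and empirical global-error estimation, analytic
    second-derivative inflection-point counting for diauxia classification
    (for simulated trajectories and for smoothed empirical activity curves),
    equilibrium location with numerical stability analysis, a with/without
    CDC6 scenario comparison, a synthetic activation-curve generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
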