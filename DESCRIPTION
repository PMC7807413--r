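Package: lungvent
Title: Local-Derivative Models of Pressure-Volume Controlled Mechanical Ventilation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-compartment lung mechanics under pressure-volume controlled
    mechanical ventilation, generalised from the classical first-order model to
    three local (memoryless) derivatives of non-integer order: the proportional
    derivative built from the PD-controller combination, the conformable
    derivative, and the truncated M-derivative. Provides the derivative,
    integral and exponential primitives of proportional calculus, the
    proportional Laplace-transform coefficient algebra for n-fold proportional
    derivatives, a proportional variation-of-parameters solver with a damped
    mass-spring application, closed-form inspiration and expiration volume
    solutions for every derivative family, residual and mean alveolar
    pressures, breath-waveform assembly, and an independent numerical oracle
    that re-integrates each model as a classical ODE to verify the closed
    forms.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
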