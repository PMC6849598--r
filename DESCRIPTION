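Package: timweb
Title: Trophic Interaction Modifications in Community Dynamics Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Build and analyse community (food-web) dynamics models in which
    consumer-resource functional responses are modified by the density of a
    third "modifier" species -- trophic interaction modifications (TIMs).
    Provides a catalogue of modification functional forms, equilibrium location
    with community (Jacobian) and net-effects matrices, a suite of TIM
    strength metrics (modification parameter and term, flux change, change in
    resource equilibrium ratio, coefficient of variation, Jacobian-element and
    Jacobian/net-effects sensitivity pairs), trajectory integration with
    dynamical classification, static-replacement and stabilisation experiments,
    parameter sweeps over TIM strength, synthetic multi-level functional
    response experiments with nonlinear least-squares fitting, model
    serialisation (JSON/YAML) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
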