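Package: iterid
Title: Iterative Identification of Nonlinear Dynamic Biochemical Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workbench for the iterative identification of nonlinear ordinary
    differential equation models of biochemical networks. Provides structural
    identifiability analysis based on power-series (Taylor and generating
    series) coefficients and identifiability tableaus, global parameter
    ranking from Latin-hypercube sampled relative sensitivities, weighted
    least-squares calibration with a hybrid scatter-search/local optimizer,
    Monte-Carlo practical identifiability analysis (solution clouds, trimmed
    ellipsoid fits, expected uncertainties), and Fisher-information based
    optimal experimental design over pulse-wise stimuli and sampling
    schedules. Ships the NF-kB regulatory-module model (15 states, 30
    parameters) as a built-in case study, together with a declarative format
    for user-defined models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
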