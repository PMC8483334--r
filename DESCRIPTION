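Package: cvdflow
Title: Stock-and-Flow System Dynamics Modelling of Cardiovascular Disease Policy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A deterministic stock-and-flow (system dynamics) simulator of acute and
    chronic cardiovascular disease in an open, ageing population aged 40 and over,
    built for strategic policy analysis. The model tracks acute coronary syndrome and
    stroke events through pre-hospital and in-hospital stages, chronic CVD in the
    community and in hospital, and competing non-CVD mortality. Eight broadly defined
    prevention and treatment strategies are applied as ramped parameter overlays and
    compared with a business-as-usual projection on deaths, hospitalisations, and
    economic net benefit (monetised QALYs, payer-stratified health-service costs,
    household costs, friction-cost productivity) under health-system and societal
    perspectives, with Latin hypercube probabilistic sensitivity analysis and
    calibration of free scaling parameters to administrative time series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    lhs,
    optparse
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    deSolve,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'params.R'
    'engine.R'
    'demography.R'
    'natural_history.R'
    'strategies.R'
    'economics.R'
    'uncertainty.R'
    'calibration.R'
    'workbench.R'
    'cli.R'
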