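Package: coursense
Title: Biomass Soft Sensor for Aerobic Fed-Batch Cultures from Cumulative
    Oxygen Uptake
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Culture-invariant estimation of biomass concentration in aerobic
    fed-batch cultivations driven solely by the cumulative oxygen uptake rate
    (cOUR) signal from off-gas analysis. Stage A identifies the Luedeking-Piret
    oxygen-consumption stoichiometry (growth yield alpha and a time-linear
    maintenance coefficient with activation time) from cOUR and sparse offline
    dry-cell-weight samples by maximising an entropy criterion with Monod-form
    uncertainty weighting, then regresses maintenance against biomass to obtain
    a strain-specific polynomial and its activation threshold X_specific.
    Stage B recursively estimates the biomass trajectory online from cOUR
    alone. A synthetic fed-batch simulator, validation metrics (MAE, MAPE,
    RMSE), CSV interchange and a command-line pipeline are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
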