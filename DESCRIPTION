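Package: brixnir
Title: Soluble Solids Prediction from Full-Transmission Vis-NIR Spectra
Version: 0.1.0
Authors@R: person("brixnir", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting tomato soluble solids content (SSC, degrees
    Brix) from online full-transmission visible/near-infrared spectra.
    Implements multi-point scan aggregation by signal-to-noise weighted
    averaging, Savitzky-Golay and standard normal variate pretreatment,
    NIPALS partial least squares regression with cross-validated latent
    variable selection, least angle regression (LARS) wavelength selection
    under L1 and L2 penalties, and repeated random-split evaluation grids.
    Ships a Beer-Lambert forward simulator of multi-point transmission scans
    for validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
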