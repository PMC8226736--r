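Package: dermavol
Title: Finite-Dose Skin Penetration Models with Volatile Vehicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Mechanistic simulation of finite-dose dermal absorption through
    the stratum corneum under two surface-boundary models: a fixed
    deposition-layer model with a saturated surface reservoir, and an
    evaporating-vehicle model in which diffusion is solubility-limited and
    ceases once the solvent has dried out. Includes the weighted error
    metrics used to assess model predictions against in vitro permeation
    test (IVPT) data, maximum-likelihood calibration of vehicle-specific
    parameters by Nelder-Mead search, AIC model comparison, a synthetic
    IVPT generator with known ground truth, and readers and writers for
    the tabular formats involved.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
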