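Package: streamtherm
Title: Stream Thermal Regimes and BACI Analysis of Riparian Thinning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how riparian canopy manipulation alters
    stream thermal regimes in replicated Before-After-Control-Impact (BACI)
    designs. Converts hourly water-temperature logger records into seasonal
    thermal-regime descriptors (MWMT, MWAT, degree days, exceedance frequency
    and duration, daily variability), estimates BACI treatment contrasts with a
    heteroscedastic linear mixed model (random site intercepts, Reach-by-Year
    residual variances) with Wald and cluster-bootstrap confidence intervals,
    builds zero-anchored longitudinal profiles of temperature change, tests
    thermal-regime structure with non-metric multidimensional scaling and
    PerMANOVA, screens environmental covariates and ranks candidate models by
    AICc, and simulates complete synthetic BACI studies with known injected
    effects for validation. Includes hemispherical-photography shade metrics
    (canopy closure, effective shade) and pyranometer light transmission.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    nlme,
    vegan,
    permute
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
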