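Package: sweatcort
Title: Blood Cortisol Estimation from Sweat by Kinetic Transport Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse modeling of cortisol transport from blood to
    sweat. Implements a compartmental kinetic model coupling Starling-driven
    capillary water filtration, free-cortisol exchange into the interstitial
    fluid, advection-diffusion transport through the interstitial fluid and
    the sweat-gland duct, entry dilution, and enzymatic (11beta-HSD2)
    conversion of cortisol to cortisone. A double-loop optimization strategy
    inverts the forward model to estimate blood cortisol concentration from
    non-invasive sweat measurements while personalizing high-sensitivity
    physiological parameters, chiefly the free-cortisol fraction. Includes
    Monte-Carlo parameter sensitivity analysis, a synthetic patient-cohort
    generator for simulation studies, and method-agreement statistics (RMSE,
    Pearson correlation with Fisher-z confidence intervals, Bland-Altman
    limits of agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
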