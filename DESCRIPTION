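Package: cmcflow
Title: Circulating Melanoma Cell Enumeration and Metastasis Risk Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for droplet-based photoacoustic enumeration of circulating
    melanoma cells (CMCs) and for threshold-based metastasis risk
    stratification in early-stage melanoma. Implements the Poisson droplet
    occupancy model for two-phase flow cytometry (droplet partitioning,
    amplitude thresholding against a noise floor, occupancy-corrected
    counting), an exact two-tailed Fisher test built from hypergeometric
    enumeration, threshold sweeps and follow-up summaries over a bundled
    38-patient study cohort, centroid/Mahalanobis cluster diagnostics in
    (day, count) space, and a proportional-hazards model with a
    time-varying longitudinal CMC covariate, including a synthetic cohort
    generator and a from-scratch partial-likelihood fitter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
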