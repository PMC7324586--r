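Package: ntcpct
Title: CT-Based Dose-Response Modelling of Radiation-Induced Lung Density Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting pixel-wise radiation dose versus CT
    Hounsfield-unit-change curves from registered planning and follow-up
    chest CT volumes and a 3D dose grid, and for fitting and comparing four
    normal tissue complication probability (NTCP) dose-response models
    (Lyman, Logit, Weibull, Poisson) in the (D50, gamma50) parameterization.
    Includes a synthetic thoracic phantom generator with known ground truth,
    threshold-based lung segmentation, rigid registration by normalized
    cross-correlation, nearest-neighbour dose-grid mapping, 6-Gy dose
    binning, goodness-of-fit statistics (SSR, adjusted R-squared, AIC, BIC),
    ANOVA-based model comparison, and a registration-error sensitivity
    experiment for the fitted D50 and gamma50 parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
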