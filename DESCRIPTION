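Package: rapidpd
Title: Rapid Quantitative Pharmacodynamic Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates quantitative pharmacodynamic parameters, principally
    the half-maximal effective concentration (EC50), from a single
    pharmacological-challenge imaging session with repeated small drug doses.
    Combines a one-compartment bolus pharmacokinetic model with a sigmoid
    Emax concentration-effect curve and polynomial baseline drift into a
    forward model of the imaging time-signal curve; fits it by an exhaustive
    grid over the nonlinear parameters with a linear least-squares subfit for
    the effect amplitude and drift coefficients; and tests goodness of fit
    against a same-degrees-of-freedom comparison polynomial with an F ratio.
    Includes a reproducible synthetic-voxel simulator, operating-
    characteristic metrics (sensitivity, specificity, positive predictive
    value of the returned EC50), volume-of-interest curve extraction and
    voxelwise fitting of 4D NIfTI volumes into parameter maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
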