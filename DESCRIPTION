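Package: condaging
Title: Quantitative Analysis of Age-Dependent Material Properties of
    Biomolecular Condensates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis stack for quantifying the age-dependent liquid-to-solid
    transition of RNA-protein condensates from fluorescence microscopy data:
    spatial autocorrelation (SAC) cluster sizing with mask-aware
    normalization, video-particle-tracking nanorheology (localization,
    linking, drift correction, mean-squared-displacement profiles,
    viscoelastic classification and Stokes-Einstein terminal viscosity),
    FRAP recovery fitting, temperature-ramp cloud-point detection with
    reversibility classification and RNA state-diagram construction, and
    droplet fusion relaxation fitting. A synthetic-data generator with known
    ground truth (Brownian/Maxwell/Kelvin-Voigt/arrested bead trajectories,
    core-shell condensate images, FRAP curves, heating-cooling ramps, force
    relaxations) makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    tiff,
    EBImage
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
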