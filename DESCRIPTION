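Package: aposcan
Title: Avian Visual Modelling and Signal-Honesty Analysis for Aposematic Prey
Version: 0.1.0
Authors@R:
    person("Aposcan", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for testing whether warning coloration
    honestly advertises chemical defence. Models prey coloration through an
    avian (blue tit) visual system: calibration of non-linear camera images
    with grey standards, polynomial mapping from camera channels to cone
    quantum catches, tetrahedral colour-space metrics (luminance,
    saturation), and receptor-noise-limited colour discrimination (just
    noticeable differences) against natural backgrounds. Quantifies toxicity
    from Daphnia dose-response bioassays (3-hour mortality summaries and
    LC50 estimation), analyses field predation on artificial prey models
    with Kaplan-Meier and stratified Cox proportional-hazards methods, and
    relates conspicuousness to toxicity and survival. Includes a synthetic
    world generator (reflectance spectra, camera images, bioassay counts,
    predation records) with known ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
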