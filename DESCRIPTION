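Package: rbcswitch
Title: Quantitative Analysis of Photoswitchable Red-Blood-Cell Membrane Area
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying light-induced membrane-area changes in
    living red blood cells. Provides sub-pixel tracking of the aspirated
    membrane tongue in micropipette brightfield image stacks, a three-section
    geometric model that converts tongue displacement into absolute and
    relative membrane-area change under volume conservation, exponential
    relaxation-time fitting of illumination cycles, suction-pressure and
    mechanical-work calculations, a decay-corrected autocorrelation pipeline
    for adherent-cell movies, a pixel-standard-deviation roughness score for
    free-floating cells, shake-flask partition-coefficient estimation with
    Beer-Lambert calibration, and inverse-Boltzmann potential-of-mean-force
    post-processing of membrane density profiles. A synthetic-data generator
    reproduces the statistical structure of every input so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
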