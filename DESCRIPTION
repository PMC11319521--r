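Package: beamproj
Title: Projection Integration of Radiotherapy Beam Profiles for Collimator Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Synthesizes treatment-plane beam profiles for small-field
    radiotherapy collimators by projecting slices of a finite focal spot
    through a stack of circular apertures and integrating their
    contributions (the projection integration method). Includes profile
    analytics (FWHM, 20-80% penumbra, peak dose-rate surrogate, detector
    volume-averaging emulation), closed-form and Monte-Carlo ray oracles
    for validation, parameter sweeps and misalignment studies for
    collimator design optimization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
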