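Package: twinlake
Title: Digital Twin Lake Modelling and Harmful Algal Bloom Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds a time-varying digital twin of a lake from a watershed
    elevation model, dynamic water levels and bathymetry soundings; extracts
    harmful-algal-bloom (HAB) extent from multiband Rayleigh-corrected
    reflectance scenes with the floating algae index (FAI); computes nearshore
    HAB coverage ratios from shore camera frames through a pluggable
    segmentation contract; and fuses satellite, video and in-situ products
    into ordered overlay scenes with 2-D ordinary kriging and 3-D anisotropic
    inverse-distance interpolation of depth-resolved water quality, including
    layer and section slicing. Ships seeded synthetic generators for every
    input so the whole pipeline is testable against analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
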