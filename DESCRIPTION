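Package: anchorTrack
Title: Single-Cell GFP Production Kinetics in Droplet Microfluidic Anchor Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing transient transfection experiments in which
    suspension cells are trapped as single cells in 2-nL droplets on a
    microfluidic anchor array and imaged by multi-channel time-lapse
    fluorescence microscopy. Provides Poisson encapsulation statistics and
    anchor-array layout models, lipoplex formulation arithmetic (hydrodynamic
    focusing dilution, molar charge ratio R+/-, per-droplet lipoplex dosing),
    a ground-truth synthetic time-lapse generator, cell segmentation with a
    size gate and per-anchor tracking, background-subtracted GFP intensity
    kinetics (delta-I traces and per-cell linear fits), and skewness-driven
    detection of a high-producer subpopulation with the supporting
    nonparametric statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
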