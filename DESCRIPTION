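Package: npquant
Title: Single-Particle Counting and Surface Carboxyl-Group Quantification
    for Nanoparticles
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a single-particle counting assay for estimating the
    molar concentration of nanoparticles immobilized in an anisotropically
    collapsed agarose microlayer, and combines it with acid-base titration
    arithmetic to report the average number of surface carboxyl groups per
    nanoparticle.  Provides a ground-truthed synthetic micrograph simulator
    (photon-upconversion and fluorescence imaging modes), diffraction-limited
    spot localization (a deterministic matched-filter detector and a small
    trainable convolutional segmentation model), background-corrected aperture
    photometry with an overlap-exclusion rule, Gaussian-mixture decomposition
    of spot-intensity histograms into monomer/dimer/trimer components with an
    aggregate correction factor, conversion of spot counts to molar
    concentration, titration endpoint arithmetic with blank correction and
    detection limits, structural interpretation metrics, and GUM-style Monte
    Carlo propagation of measurement uncertainty.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    tiff,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, SingleCell, CellBasedAssays
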