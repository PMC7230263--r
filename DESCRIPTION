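Package: perfushear
Title: Shear-Stress Simulation and Viable-Tumor-Area Quantification for
    Microchannel Tumor Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying flow-induced shear stress on adherent 3D
    tumor micronodules grown in perfusion microchannels. Solves steady
    Stokes flow around (and, via the Brinkman equations, through) an
    elliptical micronodule on a staggered finite-difference grid and
    derives normalized shear-stress and penetration-flux profiles on the
    nodule surface, with closed-form plane-channel references. Also
    implements the companion confocal image-quantification pipeline:
    adaptive-threshold segmentation of calcein-stained viability images,
    mosaic stitching with overlap fusion, maximum-intensity projection,
    composite binary masks, size-thresholded object counting with
    memory-aware cross-tile object merging, and normalization of viable
    tumor area to internal controls, together with a synthetic
    ground-truth image generator and dose-response summary statistics
    (mean +/- SEM, Welch t, Mann-Whitney, one-way ANOVA with Monte-Carlo
    Dunnett contrasts, size-cutoff sensitivity analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
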