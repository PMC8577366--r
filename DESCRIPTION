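Package: nanoelast
Title: Stain-Free Tissue Pathology from Inferred Nanomechanical Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for stain-free identification of
    tissue pathology from nanomechanical signatures. Generates synthetic
    atomic-force-microscopy (AFM) force maps and unstained brightfield images of
    tissue sections, converts force-indentation curves into elastic-modulus (EM)
    and topology maps by Hertz spherical-indenter fitting, registers measurement
    sites onto whole-sample images (coarse normalized cross-correlation, fine
    sliding-window mutual information), trains a conditional-GAN style-transfer
    network that infers per-pixel EM from unstained image intensity, and
    classifies sample pathology by unsupervised Gaussian-mixture clustering of
    EM distribution parameters with gap-statistic model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    cluster,
    jsonlite,
    tiff,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
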