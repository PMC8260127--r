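Package: radicount
Title: Seed and Radicle Detection for Parasitic Seed Germination Bioassays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying germination of parasitic
    plant seeds (Striga, Orobanche, Phelipanche) from photographs of
    bioassay disks. Provides a synthetic disk-image simulator with exact
    ground truth, Pascal VOC annotation input/output under two labeling
    schemes (non-germinated/germinated seed, or seed/radicle), a two-stage
    anchor-based object detector with a small trainable convolutional
    backbone, conversion of detections into per-disk germination rates with
    CSV batch reports, and detection (mean average precision) and counting
    (mean relative absolute error) evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    jpeg,
    xml2,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
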