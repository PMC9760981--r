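Package: meibseg
Title: Meibography Gland Segmentation with Cross-Device Histogram Harmonization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of the eyelid and meibomian-gland (MG) regions in
    infrared meibography images with a compact U-Net-style convolutional
    network (residual encoder, multi-scale dilated bottleneck), together with
    the preprocessing operators studied for cross-device harmonization
    (histogram specification to an averaged template, and contrast-limited
    adaptive histogram equalization), MG loss-rate and meiboscore
    quantification, per-region segmentation metrics, and a cross-device
    evaluation protocol. Includes a synthetic phantom generator emulating two
    acquisition devices with distinct intensity histograms so that the whole
    pipeline is testable without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    cluster,
    png,
    yaml,
    jsonlite,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
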