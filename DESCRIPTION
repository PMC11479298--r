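Package: dustscan
Title: Synthetic Paper-Sensor Images and Particle Detection for Low-Cost
    Air-Quality Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for image-based quantification of airborne particulate
    matter captured on do-it-yourself paper sensors (6 cm x 6 cm paper squares
    coated with petroleum jelly and photographed after exposure). Provides a
    seeded synthetic-image generator with exact per-particle ground truth
    (position, diameter in micrometres, grey level, PM class), camera
    degradation models (additive Gaussian noise, spatially varying focus blur,
    white-balance temperature shifts), a deterministic detection pipeline
    (grayscale conversion, Gaussian pre-blur, bicubic upscaling to a working
    resolution of 1 pixel per micrometre, local-mean adaptive thresholding and
    8-connected component extraction with equivalent-circular-diameter
    sizing), PM1/PM2.5/PM10 classification, a four-level dust-scale pollution
    rating from dot density, and a sweep harness that measures count-based
    detection accuracy across noise conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    withr,
    yaml,
    grDevices,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
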