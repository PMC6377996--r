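Package: blurbench
Title: Motion-Blur Orientation Discrimination Bench for Thalamic and
    Cortical Layer-4 Image Representations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures how linearly separable horizontal versus vertical
    motion blur is in two model representations of the early visual
    system: a thalamic (LGN) stage built from difference-of-Gaussians
    ON/OFF receptive fields sampled on a hexagonal mosaic, and a
    cortical Layer-4 stage of recurrently coupled RBF-like units
    adapted to natural-image statistics.  Ships a 1/f-spectrum
    surrogate natural-image generator, horizontal/vertical box-kernel
    motion blur, a repeated-holdout linear-SVM benchmark with accuracy
    curves over blur size, a performance-threshold report, and
    misclassification galleries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
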