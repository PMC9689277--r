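Package: mlvmf
Title: Modified Laplacian Vector Median Filtering of Impulse Noise in Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and removal of "salt and pepper" impulse noise in
    8-bit RGB and grayscale images with a two-round switching filter. A bank
    of sixteen 5x5 directional Laplacian kernels (rotation step pi/8)
    measures intensity variation around every pixel; pixels whose minimum
    absolute response across 24 kernel-channel measurements exceeds a
    threshold and whose value on the minimizing channel is 0 or 255 are
    declared impulses and replaced by the vector median of their 3x3
    neighborhood. A second round with direct-neighbor-blind kernels recovers
    clustered ("colliding") impulses that hide from neighbor-based
    detectors. Includes a seeded salt-and-pepper noise simulator with
    ground-truth masks, piecewise-smooth phantom image generators (flat,
    gradient, blocks, chest-like), a whole-image vector median filter
    baseline, and PSNR/NCD restoration-quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
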