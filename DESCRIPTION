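Package: hyperskin
Title: Calibration and Segmentation of Line-Scan Hyperspectral Skin Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automatic reflectance calibration and spectral segmentation of
    line-scan hyperspectral skin images. Reads and writes ENVI-style cubes
    (BIL/BSQ/BIP, 16-bit raw and 32-bit float payloads), removes impulse noise
    with a per-band median filter, detects a white reference stripe imaged at
    the top of the frame and uses its per-column, per-band mean brightness to
    convert raw counts to reflectance, normalizes acquisitions against a
    region-of-interest band-mean curve, segments tissue classes by mean
    absolute spectral deviation from reference spectra under manual, Otsu or
    flat-region threshold policies, and refines label maps with conditional
    morphological erosion and dilation guided by the spectral deviation map.
    Includes surface-area error accounting against expert masks and a seeded
    synthetic phantom generator with ground-truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
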