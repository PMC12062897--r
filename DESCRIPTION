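Package: wormquant
Title: Automated Per-Worm Fluorescence Quantification from Paired Brightfield Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch quantification of fluorescence in individual, non-touching
    C. elegans from paired brightfield/fluorescence micrographs. Worms are
    segmented from the brightfield channel by contrast stretching,
    illumination correction, slight blurring and Otsu thresholding; candidate
    objects are filtered by a scale-invariant "worminess" shape score
    (perimeter / (4 * sqrt(area)), about 0.89 for a circle, 1.5-2.1 for
    worms) and by minimum area. Kept masks are transferred to the raw
    fluorescence channel to record per-worm mean and standard deviation with
    per-image background subtraction (mean over all pixels outside the
    thresholded foreground), and a numbered colour overlay is written for
    manual quality control. Includes a synthetic plate generator with ground
    truth for fully offline validation, and a command-line batch driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    Rcpp,
    grDevices,
    graphics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
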