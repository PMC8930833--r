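Package: vasokymo
Title: Automated Arteriole Diameter Measurement from Two-Photon Kymographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated measurement of cortical arteriole diameter from
    two-photon time-lapse recordings, and a ground-truthed synthetic data
    generator for validating every stage. The pipeline segments the vessel,
    places up to eight scan lines perpendicular to its centerline, builds
    per-line kymographs with focus-based motion-artifact rejection, binarizes
    them with a two-Gaussian intensity mixture to obtain width traces,
    normalizes widths to the pre-pulse baseline, extracts dilation-peak
    metrics (area under the curve, maximum change, timing), applies dataset
    quality-control filters, and analyses the resulting tables with
    ln-scale linear mixed-effects models, Satterthwaite-corrected contrasts
    and difference-of-differences treatment effects reported as ratios with
    95 percent confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    EBImage,
    Matrix,
    igraph,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
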