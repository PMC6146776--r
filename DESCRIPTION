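Package: steatoscore
Title: Focused Scores for Tile-Based Quantification of Hepatic Steatosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies macrovesicular steatosis in H&E-stained liver
    sections from tile-based steatosis area fractions. Implements the
    whole-section standard score and the "focused" score family (mean and
    percentile statistics over steatotic tiles only), rule-based fat-droplet
    segmentation by saturation/brightness pixel classification and blob shape
    morphometry, clinimetric evaluation via one-way ANOVA intraclass
    correlation and Kendall's tau-b, and a synthetic section generator with
    ground-truth masks for end-to-end validation without whole-slide images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
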