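Package: bnbquant
Title: Semiquantitative Analysis of Blood-Nerve-Barrier Tight-Junction Immunofluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semiquantitative analysis of tight-junction protein
    immunofluorescence in peripheral-nerve cross sections. Implements
    ROI-based normalized immunofluorescence intensity (NIFI) with
    three-area background correction, an algorithmic detector of
    tight-junction localization in perineurial cell-cell contacts based on
    1-D line-profile peak calling (threshold subtraction, Gaussian blur,
    prominence and spacing criteria, quality-control discard rule),
    delta-Ct relative expression for qPCR, and the accompanying
    nonparametric group statistics (Friedman with Holm-Sidak post hoc,
    Kruskal-Wallis with one-sided Dunn post hoc, blinded-rater analysis).
    Includes a synthetic nerve-fascicle image generator with known ground
    truth for closed-loop validation and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
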