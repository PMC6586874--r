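Package: sicflow
Title: Subset Identification and Characterization for Cytometry Event Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated subset identification and characterization for
    flow and mass cytometry event data. Reads and writes FCS and CSV event
    tables, applies the Logicle display transformation, clusters events by
    recursive exhaustive projection pursuit over 2D projections with
    density-based merging, aligns clusters between samples with the
    quadratic-form cluster matching algorithm (QFMatch) including exhaustive
    merging to resolve cluster splits and missing populations, and displays
    cluster-level results as a multidimensional scaling embedding of cluster
    medians or as an agglomerative quadratic-form tree (QF-tree). Includes a
    synthetic Gaussian-mixture generator for paired samples and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
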