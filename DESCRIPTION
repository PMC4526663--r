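Package: catfishr
Title: Compartmental Analysis of Arc mRNA Temporal Activity (catFISH) with
    Synthetic Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying neuronal ensemble overlap from two-channel
    3D fluorescence in situ hybridization (catFISH) image stacks. Segments
    nuclei, discriminates neurons from glia, applies an optical-dissector
    sampling rule, and classifies each neuron by its Arc mRNA compartmental
    staining (negative, nuclear foci, cytoplasmic ring, or double). Converts
    classification tallies into epoch activation proportions and a similarity
    score (SiSc) measuring ensemble overlap across two behavioral epochs.
    Also quantifies synaptophysin staining as a percentage of Map2-defined
    region-of-interest area, with slide-constant automatic thresholding. A
    synthetic-data generator simulates bivariate-Bernoulli two-epoch
    recruitment and renders matching image stacks and mosaics with known
    answers, so every stage of the pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    mgcv,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
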