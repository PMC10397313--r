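Package: invasiveZone
Title: Tumor-Border Digitization and Invasive-Zone Analysis for Nanoscale Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a scanning-and-digitization model (SDM) for tumor
    borders in nanoscale spatial transcriptomics (Stereo-seq-style GEM
    tables): binning of nanoscale capture records into pseudo-spots,
    marker-score cell typing with gene-set module scores, extraction and
    spline smoothing of the tumor border from a hepatocyte mask, offset-curve
    layer construction (six 250 um layers plus distant reference bands),
    equal-area tangential tiling, spot-to-tile assignment by the
    cross-product rule, per-layer composition and signature profiling, and
    correlation-based clustering of tangential composition patterns with
    recurrence enrichment. Ships a ground-truthed synthetic-slide generator
    so the whole pipeline is testable without restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    EBImage,
    cluster,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    mgcv,
    withr,
    Seurat
Config/testthat/edition: 3
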