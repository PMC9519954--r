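Package: gliastate
Title: Transcriptome State-Change Geometry for Grafted Neural Progenitors
    and Reactive Astrocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing transcriptional state changes of neural
    progenitor cells and host astrocytes across tissue environments: gene-panel
    curation by multi-dataset vote thresholding, a two-condition
    negative-binomial differential-expression core with TMM normalization and
    an exact conditional test, panel-restricted state-change geometry (PCA
    distances, cosine similarity, congruence classification), single-nuclei
    count QC filters, radial-intensity image quantification, and a synthetic
    RNA-seq count generator with planted fold-changes and planted state-change
    angles so every stage can be scored against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    tools
Suggests:
    edgeR,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
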