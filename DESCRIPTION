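Package: mosgraphr
Title: Multi-Omics Signaling Graph Construction for Graph-AI Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts per-sample multi-omics matrices (CpG-probe methylation,
    genetic variation, transcriptomics, proteomics) plus clinical labels into
    harmonized gene-level matrices and per-sample multi-level multi-omics
    signaling graphs ready for graph neural network models. Implements
    CpG-probe-to-promoter-region binning over five TSS-anchored regions,
    gene-level aggregation (group-by mean and per-type sum), declared
    fill-value padding (0 for methylation/expression/proteomics, -1 for
    genetic variation), reference-catalog filtering, regulatory-network
    intersection, typed region/gene/protein graph assembly, edge-index
    export and deterministic k-fold splits. Includes a synthetic-study
    generator with construction-time ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
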