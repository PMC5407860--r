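Package: regwire
Title: Promoter Capture Hi-C Cis-Regulatory Unit Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of Promoter Capture Hi-C (PCHi-C) experiments
    across two cell states. Applies significance and rescue thresholding to
    CHiCAGO-style interaction scores, curates 16-state chromatin segmentations
    into broad states at restriction-fragment resolution, tests
    promoter-interacting regions for feature enrichment against
    distance-matched permutation controls, calls topologically associating
    domains from directionality indices and A/B compartments from contact
    correlation eigenvectors, assembles promoters and their interacting
    regions into cis-regulatory units (CRUs) with containment, clustering and
    state classification, and separates interaction 'rewiring' from chromatin
    'recolouring' with their association to gene expression change. Includes a
    synthetic-data generator with a planted ground-truth manifest so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
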