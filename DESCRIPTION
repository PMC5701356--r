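Package: CloneSight
Title: Alignment-Free B-Cell Clonotype Detection and Minimal Residual
    Disease Monitoring from IGH Amplicon Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects putative B-cell tumour clonotypes from IGH amplicon
    deep-sequencing reads across longitudinal samples of one patient,
    without aligning reads to a reference. Significant k-mers are selected
    by an order-of-magnitude frequency contrast between samples, combined
    into per-read signatures, clustered by Smith-Waterman similarity with a
    length-dependent score threshold, and accumulated into a multi-sample
    clone table. Clones are annotated against a germline V/D/J reference,
    filtered by diagnostic read count and germline identity, and the major
    clone's abundance is scaled to a diagnostic baseline to quantify
    minimal residual disease. A deterministic synthetic amplicon simulator
    with known clonal composition is included.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite,
    parallel,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
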