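Package: zfpkit
Title: Genome-Wide Identification and Classification of C2H2 Zinc Finger
    Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies C2H2 zinc finger proteins (ZFPs) in a proteome by
    pattern scanning (X2-Cys-X2,4-Cys-X12-His-X3,4,5-His), detects EAR
    repression motifs (LxLxL, DLNxxP), classifies fingers into the Q, QM,
    IDD, Z and C types with consensus subgroups, aggregates per-protein
    architectures (finger-count classes, tandem arrays, EAR arrangements),
    detects local gene-duplication clusters from gene order, computes
    isoelectric point and molecular weight, and tiers genes by transcript
    abundance with tissue-induction flagging. Ships a synthetic-data
    generator that plants labelled motifs, duplication clusters and
    expression patterns so the whole pipeline is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
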