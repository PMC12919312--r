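Package: isoTargetome
Title: Dual-Seed Targetome Analysis of Canonical miRNAs and Their 5'-isomiRs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare the target repertoires (targetomes) of
    canonical microRNAs and their 5'-shifted isoforms (5'-isomiRs).
    Derives shifted seed regions and mRNA-sense site motifs, scans
    transcript sequences and 3'-UTRs for 6mer and 7mer-m8 seed matches,
    normalizes paired mRNA/miRNA read-count matrices (median-of-ratios
    size factors, FPKM/RPM, log2(1+x)), screens for miRNA-mRNA
    anticorrelation with Benjamini-Hochberg control, and quantifies
    canonical-versus-isomiR targetome overlap via Jaccard indices,
    seed-enrichment odds ratios and extended-site proportions. Includes
    a synthetic-data generator that emulates the structure of paired
    tumor expression cohorts with planted seed sites and repression
    effects, so the whole pipeline is testable without external
    downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
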