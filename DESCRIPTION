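Package: methdyn
Title: Context-Specific Methylome Dynamics from Whole-Genome Bisulfite
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-based analysis of cytosine methylation dynamics across
    developmental stages from whole-genome bisulfite sequencing call tables.
    Calls methylated regions (MRs) per sequence context (CG, CHG, CHH) from
    non-overlapping 100-nt windows, calls differentially methylated regions
    (DMRs) between stages with per-bin Fisher exact tests and
    Benjamini-Hochberg false discovery control, computes annotation-overlap
    enrichment (representation factors with hypergeometric significance),
    end-aligned meta-profiles over transposable elements, saturated-CHH-site
    catalogues, small-RNA abundance over region sets, chromosome-scale stage
    ratios, and deterministically clustered DMR methylation heat matrices.
    Includes a seeded synthetic-data generator that plants known methylation
    dynamics so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
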