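Package: uromarker
Title: Urine RNA Tumor-Marker Discovery from Pooled Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and amplicon-level validation of urinary cell-free RNA
    markers for bladder cancer from pooled two-condition transcriptome data.
    Provides TPM normalization and base-10 log fold-change scoring between a
    control and a high-risk pool, multi-criteria marker filtering over coding,
    non-coding and circular transcript classes, equal-mass pool composition
    and RT-qPCR concordance checks, convergent and divergent (back-splice
    junction) primer-amplicon design with coverage analysis over splice
    variants, two-marker ratio statistics, and a seed-reproducible synthetic
    transcriptome generator so the whole pipeline is testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
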