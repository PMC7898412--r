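Package: haploMeth
Title: Haplotype-Resolved CpG Methylation from Nanopore Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to detect allele-specific CpG methylation from nanopore
    long-read sequencing of a single diploid sample. Refines single-sample
    SNV candidate calls with a pileup-feature neural-network classifier,
    assigns reads and their per-read CpG methylation calls to haplotypes
    using a phased VCF (or a trio-derived mock-phased VCF), emits
    per-haplotype methylation frequencies and mock whole-genome-bisulfite
    alignments for browser visualization, and calls differentially
    methylated regions between haplotypes with an area-statistic filter.
    Includes a synthetic diploid data generator that provides ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    pROC,
    vcfR,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
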