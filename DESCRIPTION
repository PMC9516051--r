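Package: dmrkit
Title: Dual-Context Differentially Methylated Region Calling and
    Endosperm Regulatory Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing enzymatic methyl-seq (EM-seq) and
    bisulfite-style per-cytosine methylation calls in large plant
    genomes: reading, merging and intersecting CGmap-format call files;
    calling differentially methylated regions (DMRs) on a 200-bp grid
    with concordant mCG and mCHG thresholds against an eligible
    control-region framework; characterising region sets by annotation
    overlap enrichment, end-anchored and flanking methylation profiles,
    GC content and degenerate-consensus motif matching; classifying
    small-RNA reads into siRNAs and calling siRNA-producing regions;
    classifying imprinted (maternally or paternally expressed) genes
    from allele-specific counts; and mapping causal loci from bulked
    segregant allele-frequency scans of variant tables. A synthetic
    data generator with planted ground truth emulates every input so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
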