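Package: prescan
Title: Disease Response Element Discovery from Promoter Motif Scans
Version: 0.1.0
Authors@R: person("prescan", "developers", role = c("aut", "cre"),
    email = "prescan@example.org")
Description: Tools for curating a transcription-factor binding-site motif
    dictionary (pseudocount conversion, information-content trimming,
    redundancy collapse), scanning TSS-proximal sequences with position
    weight matrices, calling differentially expressed genes from paired
    lesional/uninvolved expression data, testing motif enrichment in
    upstream regions of differentially expressed genes with semiparametric
    logistic regression, scoring risk-allele effects on motif matches at
    SNP loci, and designing complex decoy oligonucleotides. Includes a
    synthetic-data generator that emulates every pipeline input with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    jsonlite,
    withr,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
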