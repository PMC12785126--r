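Package: adipolnc
Title: Novel lncRNA Discovery and Browning-Candidate Prioritization from
    Assembled Adipocyte Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies novel long non-coding RNAs from a merged transcript
    assembly by a multi-stage filter (length, expression, known-exon
    overlap, distance to single-exon loci, coding potential), characterizes
    them against annotated lncRNAs and protein-coding genes, calls
    negative-binomial differential expression across white, brown and beige
    adipocytes, intersects contrasts, assigns cis target genes by genomic
    position and strand, and tests term enrichment. Includes a trainable
    coding-potential scorer (ORF features, Fickett TESTCODE, hexamer
    log-odds combined by logistic regression) and a synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    glmnet,
    jsonlite,
    ggplot2,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
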