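Package: dgRNAdesign
Title: Dual-Guide CRISPR Design for Whole-ORF Deletions
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Designs pairs of SpCas9 guide RNAs that excise the complete
    open-reading frame of a gene. Selects ~100 bp target regions around the
    most 5' start codon and the most 3' stop codon across all annotated
    isoforms, avoiding coding sequence of neighbouring genes; enumerates
    NGG protospacers; rejects candidates overlapping SNPs or indels from any
    of several background genomes (VCF), candidates with seed-constrained
    predicted off-targets, and low-scoring candidates under a pluggable
    position-weight efficiency model; pairs guides for deletion, emits
    G(N19) cloning oligos, and predicts wild-type and deletion-junction PCR
    amplicon sizes for diagnostic (including nested) primer sets. Ships a
    deterministic synthetic fixture generator with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
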