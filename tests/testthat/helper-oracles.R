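# Independent test-side oracles, deliberately written with base string
# operations rather than the package's Biostrings/GRanges machinery.

# reverse complement of a plain character string
rcOracle <- function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# blunt-join string surgery: drop (cut1, cut2] from a chromosome string
surgeryOracle <- function(chromStr, cut1, cut2) {
    paste0(substr(chromStr, 1L, cut1),
           substr(chromStr, cut2 + 1L, nchar(chromStr)))
}

# random uniform DNA string
rndDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")

# one-chromosome DNAStringSet
chr1 <- function(seqStr, name = "c1") {
    Biostrings::DNAStringSet(stats::setNames(seqStr, name))
}

# a minimal single-row guide GRanges with the metadata columns the
# screening/design functions expect
makeGuideRow <- function(chrom, start, strand, proto, role = "START",
                         gene = "geneX") {
    stopifnot(nchar(proto) == 20L)
    if (strand == "+") {
        pamS <- start + 20L; pamE <- start + 22L; cut <- pamS - 4L
    } else {
        pamS <- start - 3L; pamE <- start - 1L; cut <- pamE + 3L
    }
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, start + 19L),
                                 strand = strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        gene_id = gene, region_role = role, protospacer = proto,
        pam = "NGG", pam_start = pamS, pam_end = pamE,
        cut_after = cut, seed12 = substr(proto, 9, 20),
        n19 = substr(proto, 2, 20))
    gr
}

# genome with a single planted plus-strand protospacer+NGG at `at`
# (protospacer occupies at..at+19, PAM at+20..at+22)
plantedGuideGenome <- function(len = 300L, at = 101L,
                               proto = "TACGTACGTACGTACGTACG",
                               pam = "TGG") {
    s <- rndDNA(len)
    # wipe G runs so no accidental NGG/CCN sites confound the scan
    s <- gsub("G", "A", s); s <- gsub("C", "T", s)
    substr(s, at, at + 19L) <- proto
    substr(s, at + 20L, at + 22L) <- pam
    s
}

# variant GRanges with a single record
oneVariant <- function(chrom, start, end, ref = "A", alt = "T",
                       type = "SNP", label = "S2Rplus") {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), "*")
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(ref = ref, alt = alt,
                                                 type = type, label = label)
    gr
}

DIFFS <- c("CLEAN", "NESTED_ORF", "MULTI_ISOFORM", "SNP_DENSE",
           "OFFTARGET_TRAP", "SINGLE_EXON")

# does a design (or design-failure condition) match a bundle's stored truth?
matchesTruth <- function(got, truthEntry) {
    if (!is.null(truthEntry$design)) {
        d <- truthEntry$design
        inherits(got, "DeletionDesign") &&
            identical(S4Vectors::mcols(guidePair(got))$protospacer,
                      c(d$proto_start, d$proto_stop)) &&
            got@cut1 == d$cut1 && got@cut2 == d$cut2 &&
            deletionSize(got) == d$size
    } else {
        inherits(got, truthEntry$fail)
    }
}
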