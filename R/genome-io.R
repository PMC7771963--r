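#' Read a genome assembly from FASTA
#'
#' Reads a (possibly line-wrapped) multi-record FASTA into a
#' \code{DNAStringSet}. Sequence names are the first whitespace-delimited
#' token of each header; lookups elsewhere in the package are by these
#' names. Sequences are uppercased on read; only A, C, G, T and N are
#' accepted.
#'
#' @param path path to a FASTA file with at least one record.
#' @return a named \code{DNAStringSet}, record order preserved.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1 descr", "acgt"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
    if (!file.exists(path))
        stopInputError("InputError", sprintf("FASTA file not found: %s", path))
    x <- tryCatch(readDNAStringSet(path),
                  error = function(e) stopInputError("InputError",
                      sprintf("cannot parse FASTA '%s': %s", path, conditionMessage(e))))
    if (length(x) == 0L)
        stopInputError("InputError", sprintf("FASTA '%s' contains no records", path))
    names(x) <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(names(x)))
        stopInputError("InputError",
            sprintf("duplicate FASTA record name(s): %s",
                    paste(unique(names(x)[duplicated(names(x))]), collapse = ", ")))
    af <- alphabetFrequency(x, baseOnly = TRUE)
    # baseOnly 'other' pools everything outside A/C/G/T; N is tolerated,
    # any other code (incl. IUPAC ambiguity) is not
    afn <- alphabetFrequency(x)
    other <- af[, "other"] - afn[, "N"]
    if (any(other > 0L))
        stopInputError("InputError",
            sprintf("non-ACGTN characters in record(s): %s",
                    paste(names(x)[other > 0L], collapse = ", ")))
    # normalise any soft-masked (lower-case) stretches
    DNAStringSet(toupper(x))
}

#' Write a genome assembly to FASTA
#'
#' @param genome a named \code{DNAStringSet}.
#' @param path output path.
#' @param width line-wrap width.
#' @return \code{path}, invisibly.
#' @export
writeGenome <- function(genome, path, width = 70L) {
    writeXStringSet(genome, path, width = width)
    invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/CDS features linked by ID/Parent attributes into
#' \linkS4class{GeneModel} objects, one CDS chain per mRNA. GFF3 1-based
#' inclusive coordinates are kept in the package's native 1-based closed
#' convention (reports additionally emit 0-based half-open). CDS phase is
#' read but unused. CDS rows may also attach directly to a gene (treated as
#' a single-transcript gene). Genes without any CDS are dropped with a
#' warning.
#'
#' @param path path to a GFF3 file.
#' @return named list of \linkS4class{GeneModel} (names = gene IDs).
#' @export
readGeneModels <- function(path) {
    if (!file.exists(path))
        stopInputError("InputError", sprintf("GFF3 file not found: %s", path))
    gff <- rtracklayer::import(path, format = "gff3")
    typ <- as.character(gff$type)
    ids <- as.character(gff$ID)
    parents <- gff$Parent   # CharacterList
    genes <- which(typ == "gene")
    txs   <- which(typ %in% c("mRNA", "transcript"))
    cdss  <- which(typ == "CDS")
    if (length(genes) == 0L)
        stopInputError("InputError", sprintf("no gene features in '%s'", path))

    tx2gene <- setNames(vapply(parents[txs], function(p) p[1L] %||% NA_character_,
                               character(1)), ids[txs])
    geneOf <- function(fid) {
        if (fid %in% ids[genes]) fid
        else if (fid %in% names(tx2gene)) tx2gene[[fid]]
        else NA_character_
    }

    # bucket CDS rows by transcript (or gene, for parent-less annotations)
    chains <- list()
    for (i in cdss) {
        ps <- parents[[i]]
        if (length(ps) == 0L)
            stopInputError("InputError",
                sprintf("CDS feature #%d (%s:%d-%d) has no Parent attribute",
                        i, as.character(seqnames(gff))[i], start(gff)[i], end(gff)[i]))
        for (p in ps) {
            g <- geneOf(p)
            if (is.na(g))
                stopInputError("InputError",
                    sprintf("CDS feature #%d (%s:%d-%d) has unknown Parent '%s'",
                            i, as.character(seqnames(gff))[i],
                            start(gff)[i], end(gff)[i], p))
            chains[[p]] <- c(chains[[p]], i)
        }
    }

    out <- list()
    for (gi in genes) {
        gid <- ids[gi]
        txids <- c(ids[txs][tx2gene[ids[txs]] == gid], if (gid %in% names(chains)) gid)
        txids <- txids[txids %in% names(chains)]
        if (length(txids) == 0L) {
            warning(sprintf("gene '%s' has no CDS in any transcript; dropped", gid),
                    call. = FALSE)
            next
        }
        txl <- list()
        for (tid in txids) {
            rows <- chains[[tid]]
            str <- unique(as.character(strand(gff))[rows])
            if (length(str) != 1L || !str %in% c("+", "-"))
                stopInputError("InputError",
                    sprintf("transcript '%s' of gene '%s' has mixed or missing strand",
                            tid, gid))
            txl[[tid]] <- GRanges(as.character(seqnames(gff))[rows],
                                  IRanges(start(gff)[rows], end(gff)[rows]),
                                  strand = str)
        }
        chroms <- unique(vapply(txl, function(g) as.character(seqnames(g))[1L], ""))
        strs <- unique(vapply(txl, function(g) as.character(strand(g))[1L], ""))
        if (length(chroms) != 1L || length(strs) != 1L)
            stopInputError("InputError",
                sprintf("gene '%s' has transcripts on multiple chromosomes/strands", gid))
        out[[gid]] <- GeneModel(gid, chroms, strs, txl)
    }
    out
}

#' Read a labelled background variant set from VCF
#'
#' Reads SNP/indel records from a VCF (v4.x; INFO/FORMAT ignored) into a
#' \code{GRanges}. Multi-allelic rows are split into one record per ALT.
#' Each record's range is its affected reference interval
#' \code{[POS, POS + max(1, nchar(REF)) - 1]}: insertions occupy their one
#' anchor base so that an insertion anywhere under a protospacer or PAM
#' still registers as an overlap.
#'
#' @param path path to a VCF file.
#' @param label background name attached to every record (e.g. a cell-line
#'   or injection-stock identifier).
#' @param genome optional \code{DNAStringSet}; when supplied every REF
#'   allele is checked against it and a mismatch is an error.
#' @return \code{GRanges} with metadata columns \code{ref}, \code{alt},
#'   \code{type} (SNP/INS/DEL/MNP) and \code{label}.
#' @export
readVariants <- function(path, label, genome = NULL) {
    if (!file.exists(path))
        stopInputError("InputError", sprintf("VCF file not found: %s", path))
    vcf <- VariantAnnotation::readVcf(path, genome = "assembly")
    vcf <- VariantAnnotation::expand(vcf)
    rr <- SummarizedExperiment::rowRanges(vcf)
    if (length(rr) == 0L) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(ref = character(), alt = character(),
                               type = character(), label = character())
        return(gr)
    }
    ref <- as.character(rr$REF)
    alt <- as.character(rr$ALT)
    gr <- GRanges(as.character(seqnames(rr)),
                  IRanges(start(rr), width = pmax(1L, nchar(ref))),
                  strand = "*")
    type <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP",
            ifelse(nchar(alt) > nchar(ref), "INS",
            ifelse(nchar(alt) < nchar(ref), "DEL", "MNP")))
    mcols(gr) <- DataFrame(ref = ref, alt = alt, type = type, label = label)
    names(gr) <- NULL
    if (!is.null(genome)) {
        for (i in seq_along(gr)) {
            chrom <- as.character(seqnames(gr))[i]
            if (!chrom %in% names(genome))
                stopInputError("InputError",
                    sprintf("variant %d: chromosome '%s' absent from assembly", i, chrom))
            seen <- as.character(subseq(genome[[chrom]], start(gr)[i],
                                        start(gr)[i] + nchar(ref[i]) - 1L))
            if (seen != ref[i])
                stopInputError("InputError",
                    sprintf("variant %d at %s:%d: REF '%s' does not match assembly '%s'",
                            i, chrom, start(gr)[i], ref[i], seen))
        }
    }
    gr
}

#' Extract sequence for genomic intervals
#'
#' Minus-strand intervals return the reverse complement of the plus-strand
#' slice; \code{*} is treated as \code{+}.
#'
#' @param genome a named \code{DNAStringSet}.
#' @param gr a \code{GRanges} of intervals to extract.
#' @return character vector of sequences, one per interval.
#' @examples
#' g <- Biostrings::DNAStringSet(c(c1 = "ACGTT"))
#' extractSeq(g, GenomicRanges::GRanges("c1", IRanges::IRanges(2, 4), "-"))
#' @export
extractSeq <- function(genome, gr) {
    vapply(seq_along(gr), function(i) {
        chrom <- as.character(seqnames(gr))[i]
        if (!chrom %in% names(genome))
            stopInputError("InputError", sprintf("unknown chromosome '%s'", chrom))
        L <- length(genome[[chrom]])
        s <- start(gr)[i]; e <- end(gr)[i]
        if (s < 1L || e > L || s > e)
            stopInputError("InputError",
                sprintf("interval %s:%d-%d out of bounds (chromosome length %d)",
                        chrom, s, e, L))
        seq <- subseq(genome[[chrom]], s, e)
        if (as.character(strand(gr))[i] == "-")
            seq <- reverseComplement(seq)
        as.character(seq)
    }, character(1))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
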