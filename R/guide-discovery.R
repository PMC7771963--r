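# constant oligo arms of the single-tube cloning scheme: the vector is
# amplified with G(N19) fused to the scaffold arm, plus one invariant
# reverse oligo
SCAFFOLD_ARM  <- "GTTTTAGAGCTAGAAATAGC"
REVERSE_OLIGO <- "GAAGTATTGAGGAAAACATA"

revcompChr <- function(x) {
    vapply(x, function(s) {
        chartr("ACGTN", "TGCAN",
               paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
    }, character(1), USE.NAMES = FALSE)
}

#' Enumerate SpCas9 protospacer candidates in a target region
#'
#' Scans both strands of a target region for 20-nt protospacers immediately
#' 5' of an NGG PAM. The protospacer must lie fully inside the region; the
#' PAM may extend up to \code{pamSlack} (default 3) bases past the region
#' edge. Candidates whose protospacer or PAM contains an N are discarded.
#' Splice-boundary-crossing candidates are retained: the cut substrate is
#' genomic DNA.
#'
#' Each candidate records its blunt cut site \code{cut_after}: the 1-based
#' position of the last reference base 5' of the cleaved bond, which falls
#' between protospacer positions 17 and 18, i.e. 3 bp 5' of the PAM
#' (plus strand: \code{pam_start - 4}; minus strand: \code{pam_end + 3}).
#'
#' @param region a length-1 \code{GRanges} from
#'   \code{\link{selectTargetRegions}} (metadata columns \code{gene_id},
#'   \code{role} are propagated when present).
#' @param genome the assembly \code{DNAStringSet}.
#' @param param a \linkS4class{GuideDesignParam}.
#' @return \code{GRanges} of protospacer intervals (strand = guide strand),
#'   sorted by \code{cut_after} then strand, with metadata columns
#'   \code{gene_id}, \code{region_role}, \code{protospacer}, \code{pam}
#'   (both 5'->3' on the guide strand), \code{pam_start}, \code{pam_end}
#'   (reference coordinates), \code{cut_after}, \code{seed12} (the 12
#'   PAM-proximal protospacer bases) and \code{n19} (protospacer minus its
#'   5'-most base, as cloned).
#' @examples
#' g <- Biostrings::DNAStringSet(c(c1 = paste0(
#'     strrep("A", 30), "TACGTACGTACGTACGTACGTGG", strrep("A", 30))))
#' r <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 83))
#' scanProtospacers(r, g)
#' @export
scanProtospacers <- function(region, genome, param = GuideDesignParam()) {
    stopifnot(length(region) == 1L)
    chrom <- as.character(seqnames(region))
    if (!chrom %in% names(genome))
        stopInputError("InputError", sprintf("unknown chromosome '%s'", chrom))
    L <- length(genome[[chrom]])
    rs <- start(region); re <- end(region)
    slack <- param@pamSlack
    spacerLen <- param@spacerLength

    emptyOut <- function() {
        gr <- GRanges()
        mcols(gr) <- DataFrame(gene_id = character(), region_role = character(),
                               protospacer = character(), pam = character(),
                               pam_start = integer(), pam_end = integer(),
                               cut_after = integer(), seed12 = character(),
                               n19 = character())
        gr
    }
    if (re - rs + 1L < spacerLen) return(emptyOut())

    # one fetch covering the region plus PAM slack on both sides
    fs <- max(1L, rs - slack); fe <- min(L, re + slack)
    cv <- strsplit(as.character(subseq(genome[[chrom]], fs, fe)), "", fixed = TRUE)[[1]]
    at <- function(pos) cv[pos - fs + 1L]   # reference position -> base

    rows <- list()
    addRow <- function(ps, pe, strandCh, pamS, pamE, cut) {
        protoRef <- paste(at(ps:pe), collapse = "")
        pamRef <- paste(at(pamS:pamE), collapse = "")
        if (grepl("N", protoRef, fixed = TRUE) || grepl("N", pamRef, fixed = TRUE))
            return()
        proto <- if (strandCh == "+") protoRef else revcompChr(protoRef)
        pam <- if (strandCh == "+") pamRef else revcompChr(pamRef)
        rows[[length(rows) + 1L]] <<- list(
            ps = ps, pe = pe, strand = strandCh, proto = proto, pam = pam,
            pamS = pamS, pamE = pamE, cut = cut)
    }

    # plus strand: PAM starts at q; protospacer [q - 20, q - 1]
    qlo <- rs + spacerLen
    qhi <- min(re + 1L, re + slack - 2L, fe - 2L)
    if (qlo <= qhi) for (q in qlo:qhi) {
        if (!(identical(at(q + 1L), "G") && identical(at(q + 2L), "G"))) next
        addRow(q - spacerLen, q - 1L, "+", q, q + 2L, q - 4L)
    }
    # minus strand: reference CCN at [q, q + 2]; protospacer [q + 3, q + 22]
    qlo <- max(fs, rs - slack, rs - 3L)
    qhi <- re - spacerLen - 2L
    if (qlo <= qhi) for (q in qlo:qhi) {
        if (!(identical(at(q), "C") && identical(at(q + 1L), "C"))) next
        addRow(q + 3L, q + spacerLen + 2L, "-", q, q + 2L, q + 5L)
    }

    if (length(rows) == 0L) return(emptyOut())
    ps <- vapply(rows, `[[`, integer(1), "ps")
    pe <- vapply(rows, `[[`, integer(1), "pe")
    strandCh <- vapply(rows, `[[`, character(1), "strand")
    proto <- vapply(rows, `[[`, character(1), "proto")
    gr <- GRanges(chrom, IRanges(ps, pe), strand = strandCh)
    mcols(gr) <- DataFrame(
        gene_id = mcols(region)$gene_id %||% NA_character_,
        region_role = mcols(region)$role %||% NA_character_,
        protospacer = proto,
        pam = vapply(rows, `[[`, character(1), "pam"),
        pam_start = vapply(rows, `[[`, integer(1), "pamS"),
        pam_end = vapply(rows, `[[`, integer(1), "pamE"),
        cut_after = vapply(rows, `[[`, integer(1), "cut"),
        seed12 = substr(proto, 9L, 20L),
        n19 = substr(proto, 2L, 20L))
    ord <- order(mcols(gr)$cut_after, as.character(strand(gr)))
    gr[ord]
}

#' Blunt cut sites of guide candidates
#'
#' @param guides a guide \code{GRanges} from \code{\link{scanProtospacers}}.
#' @return integer vector: 1-based position of the last reference base 5'
#'   of each cut.
#' @export
cutSite <- function(guides) mcols(guides)$cut_after

#' Cloning oligos for guide candidates
#'
#' Emits the two oligos of the single-tube vector-amplification cloning
#' scheme: the forward oligo is \code{G} + the 19 PAM-proximal protospacer
#' bases (N19; the expression vector supplies the 5' G) + the 20-nt
#' scaffold arm, always 40 nt; the reverse oligo is the invariant vector
#' arm \code{GAAGTATTGAGGAAAACATA}.
#'
#' @param guides a guide \code{GRanges} from \code{\link{scanProtospacers}},
#'   or a character vector of 20-nt protospacers.
#' @return data.frame with columns \code{protospacer}, \code{forward},
#'   \code{reverse}.
#' @examples
#' cloningOligos("TACGTACGTACGTACGTACG")
#' @export
cloningOligos <- function(guides) {
    proto <- if (is.character(guides)) guides else mcols(guides)$protospacer
    stopifnot(all(nchar(proto) == 20L))
    data.frame(
        protospacer = proto,
        forward = paste0("G", substr(proto, 2L, 20L), SCAFFOLD_ARM),
        reverse = rep(REVERSE_OLIGO, length(proto)),
        stringsAsFactors = FALSE)
}
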