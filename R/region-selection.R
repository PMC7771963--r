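#' Coding anchors of a gene across all isoforms
#'
#' The two positions that define whole-ORF deletion targeting: the most 5'
#' start-codon base and the most 3' stop-codon base over every annotated
#' CDS chain. For a plus-strand gene these are the minimum CDS start and the
#' maximum CDS end; mirrored on the minus strand. Genes with alternative
#' splice forms (distinct start and/or stop codons) are thereby reduced to
#' the outermost coding span that covers every isoform.
#'
#' @param gene a \linkS4class{GeneModel}.
#' @return named integer vector \code{c(start = , stop = )}, 1-based
#'   genomic positions.
#' @examples
#' gm <- GeneModel("g", "c1", "+",
#'     list(GenomicRanges::GRanges("c1", IRanges::IRanges(101, 400))))
#' codingAnchors(gm)   # start 101, stop 400
#' @export
codingAnchors <- function(gene) {
    cds <- unlist(transcripts(gene))
    lo <- min(start(cds)); hi <- max(end(cds))
    if (gene@geneStrand == "+") c(start = lo, stop = hi)
    else                        c(start = hi, stop = lo)
}

# the CDS segment containing `pos`, searched across all transcripts;
# among containing segments pick the longest, then the leftmost, for
# determinism. Returns list(exon = GRanges row, tx = transcript name,
# exonIdx = index within that transcript's chain).
anchorExon <- function(gene, pos) {
    best <- NULL
    txl <- transcripts(gene)
    for (tname in names(txl)) {
        tx <- txl[[tname]]
        hit <- which(start(tx) <= pos & end(tx) >= pos)
        for (i in hit) {
            cand <- list(exon = tx[i], tx = tname, exonIdx = i)
            if (is.null(best) ||
                width(cand$exon) > width(best$exon) ||
                (width(cand$exon) == width(best$exon) &&
                 start(cand$exon) < start(best$exon)))
                best <- cand
        }
    }
    if (is.null(best))
        stopInputError("InputError",
            sprintf("gene '%s': no CDS segment contains position %d",
                    geneID(gene), pos))
    best
}

#' First and last coding exon
#'
#' The CDS segment containing the most 5' start codon
#' (\code{firstCodingExon}) or the most 3' stop codon
#' (\code{lastCodingExon}), searched across all isoforms. When several
#' isoforms share the anchor the longest containing segment is used
#' (leftmost on ties). For a single-exon gene both are the same segment.
#'
#' @param gene a \linkS4class{GeneModel}.
#' @return a length-1 \code{GRanges}.
#' @export
firstCodingExon <- function(gene) {
    anchorExon(gene, codingAnchors(gene)[["start"]])$exon
}

#' @rdname firstCodingExon
#' @export
lastCodingExon <- function(gene) {
    anchorExon(gene, codingAnchors(gene)[["stop"]])$exon
}

# merged CDS footprint of every gene except `excludeID` on one chromosome
foreignCDS <- function(allGenes, chrom, excludeID) {
    grl <- lapply(allGenes, function(g) {
        if (geneID(g) == excludeID || g@chrom != chrom) return(NULL)
        granges(unlist(transcripts(g)))
    })
    grl <- grl[!vapply(grl, is.null, logical(1))]
    if (length(grl) == 0L) return(GRanges())
    reduce(do.call(c, unname(grl)))
}

# ids of genes whose CDS overlaps `win`
blockingGenes <- function(allGenes, chrom, excludeID, win) {
    hits <- character()
    for (g in allGenes) {
        if (geneID(g) == excludeID || g@chrom != chrom) next
        cds <- unlist(transcripts(g))
        if (any(start(cds) <= end(win) & end(cds) >= start(win)))
            hits <- c(hits, geneID(g))
    }
    unique(hits)
}

# Slide a window of param@windowLength (>= minWindow when clipped) along an
# exon chain toward the ORF interior until it overlaps no foreign CDS.
#
# exons:   GRanges chain ordered outermost-exon first, interior-wards
# firstPlacement: for the outermost exon only, the default (anchored)
#   placement edge; NA for subsequent exons
# fromLeft: TRUE when the window's fixed edge is its left edge and sliding
#   moves right (plus-strand START / minus-strand STOP); FALSE mirrored.
slideWindow <- function(exons, firstPlacement, fromLeft, foreign, param) {
    W <- param@windowLength; Wmin <- param@minWindow
    fS <- start(foreign); fE <- end(foreign)
    exS <- start(exons); exE <- end(exons)
    clean <- function(s, e) !any(fS <= e & fE >= s)
    for (k in seq_along(exS)) {
        if (exE[k] - exS[k] + 1L < Wmin) next
        anchored <- k == 1L && !is.na(firstPlacement)
        if (fromLeft) {
            s0 <- if (anchored) firstPlacement else exS[k]
            sMax <- exE[k] - Wmin + 1L
            if (s0 > sMax) next
            for (s in s0:sMax) {
                e <- min(s + W - 1L, exE[k])
                if (clean(s, e))
                    return(list(win = IRanges(s, e), exon = k,
                                shifted = !(anchored && s == firstPlacement)))
            }
        } else {
            e0 <- if (anchored) firstPlacement else exE[k]
            eMin <- exS[k] + Wmin - 1L
            if (e0 < eMin) next
            for (e in e0:eMin) {
                s <- max(e - W + 1L, exS[k])
                if (clean(s, e))
                    return(list(win = IRanges(s, e), exon = k,
                                shifted = !(anchored && e == firstPlacement)))
            }
        }
    }
    NULL
}

#' Select the two target regions of a gene
#'
#' Derives the two ~100 bp windows in which guides are sought: the START
#' region beginning at the most 5' start codon and extending into the ORF,
#' and the STOP region ending at the most 3' stop-codon base and extending
#' back into the ORF, each clipped to its exon. When a default window would
#' overlap coding sequence of a different gene (nested or overlapping
#' ORFs), the window slides along the same transcript's CDS chain toward
#' the ORF interior - exon by exon - until a placement free of foreign CDS
#' is found; such regions are flagged \code{shifted}. Only foreign
#' \emph{CDS} blocks a window; UTR or intronic overlap with neighbours is
#' permitted. Exons shorter than \code{minWindow} are skipped.
#'
#' @param gene the \linkS4class{GeneModel} to target.
#' @param genome the assembly (\code{DNAStringSet}); used for bounds checks.
#' @param allGenes list of all \linkS4class{GeneModel}s on the assembly
#'   (including \code{gene}); the source of foreign CDS.
#' @param param a \linkS4class{GuideDesignParam}.
#' @return a length-2 \code{GRanges} (roles START, STOP) with metadata
#'   columns \code{gene_id}, \code{role}, \code{anchor} (codon anchor
#'   position), \code{shifted} and \code{rationale}.
#' @seealso \code{\link{scanProtospacers}} for the next pipeline stage.
#' @export
selectTargetRegions <- function(gene, genome, allGenes,
                                param = GuideDesignParam()) {
    anc <- codingAnchors(gene)
    chrom <- gene@chrom
    if (!chrom %in% names(genome))
        stopInputError("InputError",
            sprintf("gene '%s' is on unknown chromosome '%s'", geneID(gene), chrom))
    foreign <- foreignCDS(allGenes, chrom, geneID(gene))
    plus <- gene@geneStrand == "+"

    oneRegion <- function(role) {
        pos <- anc[[tolower(role)]]
        ae <- anchorExon(gene, pos)
        tx <- transcripts(gene)[[ae$tx]]
        # chain ordered anchor exon first, marching toward the ORF interior
        interiorRight <- (role == "START") == plus
        idx <- if (interiorRight) ae$exonIdx:length(tx) else ae$exonIdx:1
        res <- slideWindow(tx[idx], firstPlacement = pos,
                           fromLeft = interiorRight, foreign = foreign,
                           param = param)
        if (is.null(res)) {
            allwin <- range(tx)
            stopNoCleanRegion(geneID(gene), role,
                blockingGenes(allGenes, chrom, geneID(gene), allwin) %||% "none")
        }
        gr <- GRanges(chrom, res$win, strand = gene@geneStrand)
        mcols(gr) <- DataFrame(
            gene_id = geneID(gene), role = role, anchor = unname(pos),
            shifted = res$shifted,
            rationale = if (res$shifted)
                sprintf("default window overlapped foreign CDS; moved interior-ward to CDS segment %d of transcript %s",
                        idx[res$exon], ae$tx)
            else sprintf("default window anchored at %s codon", tolower(role)))
        gr
    }

    c(oneRegion("START"), oneRegion("STOP"))
}
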