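# count of variants within `flank` bp of the guide footprint, used as a
# ranking key: among clean guides, prefer those in locally variant-poor
# sequence (more robust to imperfect background catalogues)
variantAdjacency <- function(guides, variants, flank = 10L) {
    if (length(variants) == 0L) return(integer(length(guides)))
    fp <- footprintVectors(guides)
    vChrom <- as.character(seqnames(variants))
    vS <- start(variants); vE <- end(variants)
    vapply(seq_along(fp$s), function(i) {
        sum(vChrom == fp$chrom[i] & vS <= fp$e[i] + flank & vE >= fp$s[i] - flank)
    }, integer(1))
}

#' Rank screened guide candidates
#'
#' Orders the PASS candidates of one region: efficiency score descending,
#' then fewer variants in the 10 bp flanks of the site, then cut position
#' ascending, then plus strand before minus. Deterministic for identical
#' inputs.
#'
#' @param guides guide \code{GRanges}.
#' @param screen the \code{DataFrame} from \code{\link{screenGuides}} for
#'   the same guides.
#' @param variants \code{GRanges} of background variants (for the
#'   flank-adjacency tie-break; may be empty).
#' @return integer vector: indices into \code{guides} of the PASS
#'   candidates, best first.
#' @export
rankCandidates <- function(guides, screen, variants = GRanges()) {
    stopifnot(length(guides) == nrow(screen))
    idx <- which(screen$verdict == "PASS")
    if (length(idx) == 0L) return(integer())
    adj <- variantAdjacency(guides[idx], variants)
    # scores are compared rounded so that sub-nanoscale floating-point
    # noise cannot flip a tie-break
    ord <- order(-round(screen$efficiency[idx], 9L), adj,
                 mcols(guides)$cut_after[idx],
                 as.character(strand(guides))[idx])
    idx[ord]
}

#' Design a whole-ORF deletion for one gene
#'
#' Runs the full per-gene pipeline: select the START and STOP target
#' regions, enumerate protospacer candidates in each, screen every
#' candidate against all background variant sets and for predicted
#' off-targets, and pick the best PASS pair whose cuts are at least
#' \code{minSeparation} apart. The pair score is the summed efficiency of
#' the two guides (ties broken by START then STOP cut coordinate), and up
#' to \code{nAlternates} runner-up pairs are retained so that a failed
#' construct can be re-attempted with the next pair without re-running the
#' design. Cloning oligos for both chosen guides are emitted.
#'
#' @param gene the \linkS4class{GeneModel} to delete.
#' @param genome the assembly \code{DNAStringSet}.
#' @param allGenes list of every \linkS4class{GeneModel} on the assembly.
#' @param variants \code{GRanges} of labelled background variants.
#' @param param a \linkS4class{GuideDesignParam}.
#' @return a \linkS4class{DeletionDesign}.
#' @seealso \code{\link{designGenes}} for the multi-gene driver,
#'   \code{\link{predictAmplicon}} for diagnostic PCR prediction.
#' @export
designDeletion <- function(gene, genome, allGenes = list(gene),
                           variants = GRanges(), param = GuideDesignParam()) {
    regions <- selectTargetRegions(gene, genome, allGenes, param)
    gStart <- scanProtospacers(regions[1], genome, param)
    gStop  <- scanProtospacers(regions[2], genome, param)
    if (length(gStart) == 0L)
        stopNoViablePair(geneID(gene), "scanning", "no protospacer in the START region")
    if (length(gStop) == 0L)
        stopNoViablePair(geneID(gene), "scanning", "no protospacer in the STOP region")
    scStart <- screenGuides(gStart, genome, variants, param)
    scStop  <- screenGuides(gStop, genome, variants, param)
    okStart <- rankCandidates(gStart, scStart, variants)
    okStop  <- rankCandidates(gStop, scStop, variants)
    if (length(okStart) == 0L)
        stopNoViablePair(geneID(gene), "screening", "no PASS guide in the START region")
    if (length(okStop) == 0L)
        stopNoViablePair(geneID(gene), "screening", "no PASS guide in the STOP region")

    # exhaustive PASS x PASS grid under the separation constraint
    grid <- expand.grid(i = okStart, j = okStop)
    cutS <- mcols(gStart)$cut_after[grid$i]
    cutT <- mcols(gStop)$cut_after[grid$j]
    sep <- abs(cutT - cutS)
    grid <- grid[sep >= param@minSeparation, , drop = FALSE]
    if (nrow(grid) == 0L)
        stopNoViablePair(geneID(gene), "pairing",
            sprintf("no PASS pair with cut separation >= %d bp",
                    param@minSeparation))
    effSum <- round(scStart$efficiency[grid$i] + scStop$efficiency[grid$j], 9L)
    ord <- order(-effSum,
                 mcols(gStart)$cut_after[grid$i],
                 mcols(gStop)$cut_after[grid$j])
    grid <- grid[ord, , drop = FALSE]

    mk <- function(r) {
        g1 <- gStart[grid$i[r]]; g2 <- gStop[grid$j[r]]
        c1 <- mcols(g1)$cut_after; c2 <- mcols(g2)$cut_after
        list(g1 = g1, g2 = g2,
             cutLo = min(c1, c2), cutHi = max(c1, c2),
             eff = scStart$efficiency[grid$i[r]] + scStop$efficiency[grid$j[r]])
    }
    best <- mk(1L)
    nalt <- min(param@nAlternates, nrow(grid) - 1L)
    alternates <- if (nalt > 0L) {
        do.call(rbind, lapply(seq_len(nalt) + 1L, function(r) {
            a <- mk(r)
            data.frame(rank = r - 1L,
                       protospacer_start = mcols(a$g1)$protospacer,
                       protospacer_stop = mcols(a$g2)$protospacer,
                       cut1 = a$cutLo, cut2 = a$cutHi,
                       deletion_size = a$cutHi - a$cutLo,
                       efficiency_sum = a$eff,
                       stringsAsFactors = FALSE)
        }))
    } else {
        data.frame(rank = integer(), protospacer_start = character(),
                   protospacer_stop = character(), cut1 = integer(),
                   cut2 = integer(), deletion_size = integer(),
                   efficiency_sum = numeric(), stringsAsFactors = FALSE)
    }
    oligos <- cbind(role = c("START", "STOP"),
                    cloningOligos(c(best$g1, best$g2)),
                    stringsAsFactors = FALSE)
    new("DeletionDesign",
        geneID = geneID(gene), chrom = gene@chrom,
        guideStart = best$g1, guideStop = best$g2,
        cut1 = as.integer(best$cutLo), cut2 = as.integer(best$cutHi),
        deletionSize = as.integer(best$cutHi - best$cutLo),
        oligos = oligos, alternates = alternates, param = param)
}

#' Predicted deletion of a design
#'
#' Under the blunt re-ligation repair model the excised reference bases
#' are \code{(cut1, cut2]} and the re-ligated allele is the reference with
#' that interval removed; junction indel diversity is out of scope (the
#' blunt model is what diagnostic amplicon arithmetic uses).
#'
#' @param design a \linkS4class{DeletionDesign}.
#' @return list with \code{interval} (a \code{GRanges} of the excised
#'   1-based bases) and \code{size} (bp).
#' @export
predictedDeletion <- function(design) {
    list(interval = deletionInterval(design), size = deletionSize(design))
}

#' Construct the blunt-join deletion allele
#'
#' @param design a \linkS4class{DeletionDesign}.
#' @param genome the reference assembly \code{DNAStringSet}.
#' @return a \code{DNAStringSet}: the reference with the excised interval
#'   removed from the design's chromosome, other sequences unchanged.
#' @export
deletionAllele <- function(design, genome) {
    chrom <- design@chrom
    if (!chrom %in% names(genome))
        stopInputError("InputError", sprintf("unknown chromosome '%s'", chrom))
    ref <- genome[[chrom]]
    L <- length(ref)
    if (design@cut2 > L)
        stopInputError("InputError", "deletion interval exceeds chromosome length")
    left <- if (design@cut1 >= 1L) subseq(ref, 1L, design@cut1) else DNAString("")
    right <- if (design@cut2 < L) subseq(ref, design@cut2 + 1L, L) else DNAString("")
    out <- genome
    out[[chrom]] <- DNAString(paste0(as.character(left), as.character(right)))
    out
}

#' Deletion junction sequence
#'
#' @param design a \linkS4class{DeletionDesign}.
#' @param genome the reference assembly.
#' @param flank bases of flank on each side of the junction.
#' @return character scalar: \code{flank} bases 5' of the junction followed
#'   by \code{flank} bases 3' of it, on the re-ligated allele.
#' @export
junctionSequence <- function(design, genome, flank = 30L) {
    ref <- genome[[design@chrom]]
    lo <- max(1L, design@cut1 - flank + 1L)
    hi <- min(length(ref), design@cut2 + flank)
    paste0(as.character(subseq(ref, lo, design@cut1)),
           as.character(subseq(ref, design@cut2 + 1L, hi)))
}
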