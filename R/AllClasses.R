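#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement subseq
#'   readDNAStringSet writeXStringSet vmatchPattern matchPattern alphabetFrequency
#' @importFrom GenomeInfoDb seqlengths seqlevels
#' @importFrom stats setNames
#' @importFrom utils write.table read.delim
NULL

#' Gene model: one gene with one or more coding-sequence chains
#'
#' A \code{GeneModel} holds the CDS structure of a single gene: one
#' \linkS4class{GRangesList} element per transcript, each a chain of CDS
#' segments in genomic order on a single chromosome and strand.  Multiple
#' transcripts capture alternative splice forms with distinct start and/or
#' stop codons; region selection works from the most 5' start codon and the
#' most 3' stop codon over all chains.
#'
#' @slot geneID single gene identifier.
#' @slot chrom chromosome (sequence) name.
#' @slot geneStrand \code{"+"} or \code{"-"}.
#' @slot transcripts named \code{GRangesList}; each element the CDS segments
#'   of one transcript, sorted, non-overlapping, all on \code{chrom}.
#'
#' @aliases GeneModel-class
#' @exportClass GeneModel
setClass("GeneModel",
    representation(
        geneID      = "character",
        chrom       = "character",
        geneStrand  = "character",
        transcripts = "GRangesList"
    )
)

setValidity("GeneModel", function(object) {
    msg <- character()
    if (length(object@geneID) != 1L || !nzchar(object@geneID))
        msg <- c(msg, "geneID must be a single non-empty string")
    if (!object@geneStrand %in% c("+", "-"))
        msg <- c(msg, "geneStrand must be '+' or '-'")
    if (length(object@transcripts) < 1L)
        msg <- c(msg, "at least one transcript is required")
    for (i in seq_along(object@transcripts)) {
        tx <- object@transcripts[[i]]
        if (length(tx) < 1L) {
            msg <- c(msg, sprintf("transcript %d has no CDS segments", i))
            next
        }
        if (!all(as.character(seqnames(tx)) == object@chrom))
            msg <- c(msg, sprintf("transcript %d has CDS off chromosome '%s'",
                                  i, object@chrom))
        st <- start(tx)
        if (is.unsorted(st))
            msg <- c(msg, sprintf("transcript %d CDS segments not sorted", i))
        if (length(tx) > 1L && any(start(tx)[-1L] <= end(tx)[-length(tx)]))
            msg <- c(msg, sprintf("transcript %d CDS segments overlap", i))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GeneModel
#'
#' @param geneID gene identifier.
#' @param chrom chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param transcripts a list (or \code{GRangesList}) of CDS-segment
#'   \code{GRanges}, one element per transcript.  Segments are sorted on
#'   construction.
#' @return a \linkS4class{GeneModel}.
#' @examples
#' gm <- GeneModel("geneA", "chr1", "+",
#'     list(t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 40))))
#' codingAnchors(gm)
#' @export
GeneModel <- function(geneID, chrom, strand, transcripts) {
    txl <- lapply(transcripts, function(tx) {
        tx <- GRanges(seqnames = as.character(seqnames(tx)),
                      ranges = IRanges(start(tx), end(tx)),
                      strand = strand)
        sort(tx)
    })
    if (is.null(names(txl)) || any(!nzchar(names(txl))))
        names(txl) <- paste0(geneID, ".t", seq_along(txl))
    new("GeneModel", geneID = geneID, chrom = chrom, geneStrand = strand,
        transcripts = GRangesList(txl))
}

#' Screening and design parameters
#'
#' Bundles every tunable used along the design pipeline so that a whole run
#' is reproducible from one object; the serialized parameter set is embedded
#' in every report.
#'
#' @slot windowLength target-region length in bp (default 100).
#' @slot minWindow smallest acceptable clipped region, bp (default 30).
#' @slot spacerLength protospacer length scanned and matched (20).
#' @slot pamSlack how far (bp) the PAM may extend past the region edge
#'   (default 3).
#' @slot maxMMTotal off-target search: maximum protospacer mismatches
#'   (default 3).
#' @slot maxMMSeed off-target search: maximum mismatches in the 12-nt
#'   PAM-proximal seed (default 0).
#' @slot offtargetPAMs PAM classes admitted as off-target sites
#'   (default NGG and NAG).
#' @slot minSeparation minimum distance between the two cuts, bp
#'   (default 200).
#' @slot efficiencyFloor minimum efficiency score for a PASS verdict
#'   (default 0: efficiency ranks, it does not reject).
#' @slot efficiencyWeights 4 x 20 numeric weight matrix, rows A,C,G,T,
#'   columns protospacer positions 1 (PAM-distal) to 20 (PAM-proximal).
#' @slot maxAmplifiable largest PCR product called detectable, bp
#'   (default 5000).
#' @slot warnAmplifiable products up to this size are flagged as
#'   borderline rather than undetectable (default 10000).
#' @slot nAlternates number of runner-up guide pairs kept (default 5).
#'
#' @aliases GuideDesignParam-class
#' @exportClass GuideDesignParam
setClass("GuideDesignParam",
    representation(
        windowLength      = "integer",
        minWindow         = "integer",
        spacerLength      = "integer",
        pamSlack          = "integer",
        maxMMTotal        = "integer",
        maxMMSeed         = "integer",
        offtargetPAMs     = "character",
        minSeparation     = "integer",
        efficiencyFloor   = "numeric",
        efficiencyWeights = "matrix",
        maxAmplifiable    = "integer",
        warnAmplifiable   = "integer",
        nAlternates       = "integer"
    )
)

setValidity("GuideDesignParam", function(object) {
    msg <- character()
    pos <- c(windowLength = object@windowLength, minWindow = object@minWindow,
             spacerLength = object@spacerLength, minSeparation = object@minSeparation,
             maxAmplifiable = object@maxAmplifiable, nAlternates = object@nAlternates)
    if (any(pos <= 0L))
        msg <- c(msg, paste("non-positive parameter:",
                            paste(names(pos)[pos <= 0L], collapse = ", ")))
    if (object@pamSlack < 0L || object@maxMMTotal < 0L || object@maxMMSeed < 0L)
        msg <- c(msg, "pamSlack, maxMMTotal and maxMMSeed must be >= 0")
    if (object@maxMMSeed > object@maxMMTotal)
        msg <- c(msg, "maxMMSeed cannot exceed maxMMTotal")
    if (!all(object@offtargetPAMs %in% c("NGG", "NAG")))
        msg <- c(msg, "offtargetPAMs must be a subset of {NGG, NAG}")
    if (!identical(dim(object@efficiencyWeights), c(4L, 20L)))
        msg <- c(msg, "efficiencyWeights must be a 4 x 20 matrix (rows A,C,G,T)")
    if (!identical(rownames(object@efficiencyWeights), c("A", "C", "G", "T")))
        msg <- c(msg, "efficiencyWeights rows must be named A,C,G,T")
    if (any(is.na(object@efficiencyWeights)))
        msg <- c(msg, "efficiencyWeights must be complete (no NA)")
    if (object@minWindow > object@windowLength)
        msg <- c(msg, "minWindow cannot exceed windowLength")
    if (length(msg)) msg else TRUE
})

#' A full deletion design for one gene
#'
#' The ordered pair of screened guides (one in the start-codon region, one in
#' the stop-codon region), the predicted blunt-join deletion, the cloning
#' oligos for both guides, ranked runner-up pairs for the bench retry loop,
#' and the parameter snapshot.
#'
#' @slot geneID target gene.
#' @slot chrom chromosome.
#' @slot guideStart,guideStop single-row guide \code{GRanges} (see
#'   \code{\link{scanProtospacers}} for columns).
#' @slot cut1,cut2 1-based position of the last reference base 5' of each
#'   blunt cut; \code{cut1 < cut2}.
#' @slot deletionSize \code{cut2 - cut1} in bp.
#' @slot oligos two-row data.frame of cloning oligos (role, forward, reverse).
#' @slot alternates data.frame of runner-up pairs (may have zero rows).
#' @slot param the \linkS4class{GuideDesignParam} used.
#'
#' @aliases DeletionDesign-class
#' @exportClass DeletionDesign
setClass("DeletionDesign",
    representation(
        geneID       = "character",
        chrom        = "character",
        guideStart   = "GRanges",
        guideStop    = "GRanges",
        cut1         = "integer",
        cut2         = "integer",
        deletionSize = "integer",
        oligos       = "data.frame",
        alternates   = "data.frame",
        param        = "GuideDesignParam"
    )
)

setValidity("DeletionDesign", function(object) {
    msg <- character()
    if (length(object@guideStart) != 1L || length(object@guideStop) != 1L)
        msg <- c(msg, "guideStart and guideStop must each hold exactly one guide")
    if (length(object@guideStart) == 1L &&
        !identical(mcols(object@guideStart)$region_role, "START"))
        msg <- c(msg, "guideStart must come from the START region")
    if (length(object@guideStop) == 1L &&
        !identical(mcols(object@guideStop)$region_role, "STOP"))
        msg <- c(msg, "guideStop must come from the STOP region")
    if (object@cut1 >= object@cut2)
        msg <- c(msg, "cut1 must lie 5' of cut2 on the reference")
    if (object@deletionSize != object@cut2 - object@cut1)
        msg <- c(msg, "deletionSize must equal cut2 - cut1")
    if (object@deletionSize < object@param@minSeparation)
        msg <- c(msg, "deletion smaller than the configured minimum separation")
    if (length(msg)) msg else TRUE
})

#' Predicted PCR outcome for one primer pair
#'
#' Wild-type and deletion-allele product sizes for an exact-match primer
#' pair, with detectability calls under the configured maximum amplifiable
#' length and a small-product amplification-bias flag: when the deletion
#' product is shorter than the wild-type product, the deletion band tends to
#' outcompete the wild-type band in a mixed template.
#'
#' @slot pairName primer pair label.
#' @slot tier \code{"OUTER"}, \code{"INNER"} or \code{"SINGLE"}.
#' @slot status \code{"OK"} or one of \code{"AmbiguousPrimer"},
#'   \code{"PrimerLost"}, \code{"Divergent"}, \code{"NoProduct"}.
#' @slot wtSize,delSize product sizes in bp (\code{NA} when the allele
#'   yields no product); sizes span the 5' end of the forward primer to the
#'   5' end of the reverse primer, inclusive.
#' @slot wtDetectable,delDetectable size <= maxAmplifiable.
#' @slot biasNote non-empty when \code{delSize < wtSize}.
#' @slot detail free-text audit note (which primer failed, warn tier, ...).
#'
#' @aliases AmpliconPrediction-class
#' @exportClass AmpliconPrediction
setClass("AmpliconPrediction",
    representation(
        pairName      = "character",
        tier          = "character",
        status        = "character",
        wtSize        = "integer",
        delSize       = "integer",
        wtDetectable  = "logical",
        delDetectable = "logical",
        biasNote      = "character",
        detail        = "character"
    )
)

#' A deterministic synthetic test fixture with recorded ground truth
#'
#' One synthetic genome with planted gene models, labelled variant
#' backgrounds and (difficulty-dependent) hazards, plus the ground truth
#' established at generation time by the naive brute-force oracles in this
#' module. Regeneration from the same seed is byte-identical.
#'
#' @slot seed integer seed the bundle was generated from.
#' @slot difficulty one of CLEAN, NESTED_ORF, MULTI_ISOFORM, SNP_DENSE,
#'   OFFTARGET_TRAP, SINGLE_EXON.
#' @slot genome \code{DNAStringSet}.
#' @slot genes list of \linkS4class{GeneModel}.
#' @slot variants \code{GRanges} with columns ref, alt, type, label
#'   (two labels by default, emulating a cell-line and an injection-stock
#'   background).
#' @slot truth list of oracle-verified expectations (regions, expected
#'   design or the expected failure, amplicon sizes when primers planted).
#'
#' @aliases FixtureBundle-class
#' @exportClass FixtureBundle
setClass("FixtureBundle",
    representation(
        seed       = "integer",
        difficulty = "character",
        genome     = "DNAStringSet",
        genes      = "list",
        variants   = "GRanges",
        truth      = "list"
    )
)

setMethod("show", "GeneModel", function(object) {
    ntx <- length(object@transcripts)
    cds <- unlist(object@transcripts)
    cat(sprintf("GeneModel '%s' on %s(%s): %d transcript%s, CDS footprint %d-%d\n",
                object@geneID, object@chrom, object@geneStrand,
                ntx, if (ntx == 1L) "" else "s",
                min(start(cds)), max(end(cds))))
})

setMethod("show", "GuideDesignParam", function(object) {
    cat("GuideDesignParam:\n")
    cat(sprintf("  region window %d bp (min %d); protospacer %d nt, PAM slack %d\n",
                object@windowLength, object@minWindow,
                object@spacerLength, object@pamSlack))
    cat(sprintf("  off-targets: <=%d total mismatches, <=%d in 12-nt seed, PAMs %s\n",
                object@maxMMTotal, object@maxMMSeed,
                paste(object@offtargetPAMs, collapse = "/")))
    cat(sprintf("  min cut separation %d bp; efficiency floor %.2f; max amplicon %d bp\n",
                object@minSeparation, object@efficiencyFloor,
                object@maxAmplifiable))
})

setMethod("show", "DeletionDesign", function(object) {
    cat(sprintf("DeletionDesign for '%s' on %s\n", object@geneID, object@chrom))
    cat(sprintf("  guide 1 (START): %s | cut after %d\n",
                mcols(object@guideStart)$protospacer, object@cut1))
    cat(sprintf("  guide 2 (STOP):  %s | cut after %d\n",
                mcols(object@guideStop)$protospacer, object@cut2))
    cat(sprintf("  deletion: %d-%d (1-based excised bases), %d bp; %d alternate pair%s\n",
                object@cut1 + 1L, object@cut2, object@deletionSize,
                nrow(object@alternates),
                if (nrow(object@alternates) == 1L) "" else "s"))
})

setMethod("show", "AmpliconPrediction", function(object) {
    fmt <- function(x) if (is.na(x)) "none" else sprintf("%d bp", x)
    cat(sprintf("AmpliconPrediction '%s' [%s] (%s): WT %s, deletion %s\n",
                object@pairName, object@tier, object@status,
                fmt(object@wtSize), fmt(object@delSize)))
    if (nzchar(object@biasNote)) cat("  note:", object@biasNote, "\n")
})

setMethod("show", "FixtureBundle", function(object) {
    cat(sprintf("FixtureBundle seed=%d difficulty=%s: genome %d bp, %d gene%s, %d variants (%s)\n",
                object@seed, object@difficulty,
                sum(width(object@genome)), length(object@genes),
                if (length(object@genes) == 1L) "" else "s",
                length(object@variants),
                paste(unique(mcols(object@variants)$label), collapse = "+")))
})
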