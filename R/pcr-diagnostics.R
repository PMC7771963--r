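#' Read a primer table
#'
#' Tab-separated with columns \code{name}, \code{forward}, \code{reverse}
#' and optional \code{tier} (OUTER/INNER/SINGLE; default SINGLE). Primers
#' must be 15-40 nt over A/C/G/T.
#'
#' @param path TSV path.
#' @return data.frame with validated columns.
#' @export
readPrimerTable <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("name", "forward", "reverse")
    if (!all(need %in% names(tab)))
        stopInputError("InputError",
            sprintf("primer table must have columns %s", paste(need, collapse = ", ")))
    if (is.null(tab$tier)) tab$tier <- "SINGLE"
    tab$forward <- toupper(tab$forward); tab$reverse <- toupper(tab$reverse)
    for (col in c("forward", "reverse")) {
        bad <- !grepl("^[ACGT]{15,40}$", tab[[col]])
        if (any(bad))
            stopInputError("InputError",
                sprintf("%s primer of '%s' must be 15-40 nt over ACGT",
                        col, paste(tab$name[bad], collapse = ", ")))
    }
    if (!all(tab$tier %in% c("OUTER", "INNER", "SINGLE")))
        stopInputError("InputError", "tier must be OUTER, INNER or SINGLE")
    tab
}

#' Locate exact primer annealing sites
#'
#' Exact-match occurrences of a primer on both strands of an assembly (or
#' of a deletion allele). A plus-strand site means the primer sequence
#' reads 5'->3' left to right at that interval; a minus-strand site means
#' the reverse complement does (the primer anneals to the plus strand and
#' extends leftwards).
#'
#' @param seqs a \code{DNAStringSet}.
#' @param primer character scalar over A/C/G/T (15-40 nt).
#' @return \code{GRanges} of sites, strand set accordingly (may be empty).
#' @export
locatePrimer <- function(seqs, primer) {
    if (!grepl("^[ACGT]+$", primer))
        stopInputError("InputError",
            sprintf("primer '%s' contains characters outside ACGT", primer))
    pat <- DNAString(primer)
    rcp <- reverseComplement(pat)
    chroms <- character(); s <- integer(); e <- integer(); str <- character()
    for (chrom in names(seqs)) {
        m <- matchPattern(pat, seqs[[chrom]])
        if (length(m)) {
            chroms <- c(chroms, rep(chrom, length(m)))
            s <- c(s, start(m)); e <- c(e, end(m))
            str <- c(str, rep("+", length(m)))
        }
        m <- matchPattern(rcp, seqs[[chrom]])
        if (length(m)) {
            chroms <- c(chroms, rep(chrom, length(m)))
            s <- c(s, start(m)); e <- c(e, end(m))
            str <- c(str, rep("-", length(m)))
        }
    }
    if (length(s) == 0L) return(GRanges())
    o <- order(chroms, s, str)
    GRanges(chroms[o], IRanges(s[o], e[o]), strand = str[o])
}

# unique-site lookup used by predictAmplicon; returns GRanges row or a
# status string
uniqueSite <- function(seqs, primer) {
    sites <- locatePrimer(seqs, primer)
    if (length(sites) == 0L) return("unmapped")
    if (length(sites) > 1L) return("ambiguous")
    sites
}

#' Predict diagnostic PCR products on the reference and a deletion allele
#'
#' Computes the wild-type product size for a primer pair on the reference
#' and, when a \linkS4class{DeletionDesign} is given, the deletion-junction
#' product on the blunt-join allele. Sizes follow the standard gel
#' convention: 5' end of the forward primer to the 5' end of the reverse
#' primer, inclusive of both primer footprints, so for a deletion spanned
#' by both primers \code{wt_size - del_size} equals the deletion size.
#' Primer orientation is normalised: if the pair converges with the roles
#' swapped, they are swapped back, so predictions do not depend on which
#' primer was labelled forward.
#'
#' Statuses instead of exceptions (audit friendliness):
#' \code{AmbiguousPrimer} (a primer maps more than once),
#' \code{Divergent} (primers on different chromosomes or not convergent),
#' \code{PrimerLost} (a primer site lies inside the deleted interval, so
#' the deletion allele yields no product), \code{NoProduct} (a primer does
#' not map at all).
#'
#' A product is \code{detectable} when its size is at most
#' \code{maxAmplifiable} (default 5000 bp; sizes up to
#' \code{warnAmplifiable} are noted as borderline in \code{detail}).
#' When both alleles amplify and the deletion product is smaller, the
#' prediction carries a bias note: in a mixed template the shorter product
#' tends to dominate, so absence of the wild-type band from an edited
#' sample is expected, not anomalous.
#'
#' @param name primer pair label.
#' @param forward,reverse primer sequences (5'->3').
#' @param genome reference assembly \code{DNAStringSet}.
#' @param design optional \linkS4class{DeletionDesign}.
#' @param param a \linkS4class{GuideDesignParam}.
#' @param tier OUTER, INNER or SINGLE (bookkeeping only).
#' @return an \linkS4class{AmpliconPrediction}.
#' @export
predictAmplicon <- function(name, forward, reverse, genome, design = NULL,
                            param = GuideDesignParam(), tier = "SINGLE") {
    mkPred <- function(status, wt = NA_integer_, del = NA_integer_, detail = "") {
        bias <- if (!is.na(wt) && !is.na(del) && del < wt)
            sprintf("deletion product (%d bp) smaller than wild-type (%d bp): expect the deletion band to outcompete the wild-type band in mixed template", del, wt)
        else ""
        new("AmpliconPrediction", pairName = name, tier = tier,
            status = status,
            wtSize = as.integer(wt), delSize = as.integer(del),
            wtDetectable = !is.na(wt) && wt <= param@maxAmplifiable,
            delDetectable = !is.na(del) && del <= param@maxAmplifiable,
            biasNote = bias, detail = detail)
    }

    fSite <- uniqueSite(genome, forward)
    rSite <- uniqueSite(genome, reverse)
    if (identical(fSite, "unmapped") || identical(rSite, "unmapped"))
        return(mkPred("NoProduct", detail = sprintf(
            "unmapped primer(s): %s",
            paste(c(if (identical(fSite, "unmapped")) "forward",
                    if (identical(rSite, "unmapped")) "reverse"), collapse = ", "))))
    if (identical(fSite, "ambiguous") || identical(rSite, "ambiguous"))
        return(mkPred("AmbiguousPrimer", detail = sprintf(
            "multi-site primer(s): %s",
            paste(c(if (identical(fSite, "ambiguous")) "forward",
                    if (identical(rSite, "ambiguous")) "reverse"), collapse = ", "))))
    if (as.character(seqnames(fSite)) != as.character(seqnames(rSite)))
        return(mkPred("Divergent", detail = "primers map to different chromosomes"))

    # orientation normalisation: need a (+) site left of a (-) site
    sF <- as.character(strand(fSite)); sR <- as.character(strand(rSite))
    swapped <- FALSE
    if (sF == "-" && sR == "+") {
        tmp <- fSite; fSite <- rSite; rSite <- tmp
        sF <- "+"; sR <- "-"; swapped <- TRUE
    }
    if (!(sF == "+" && sR == "-") || start(fSite) > start(rSite))
        return(mkPred("Divergent",
            detail = "primer pair does not converge on this template"))
    wt <- end(rSite) - start(fSite) + 1L

    if (is.null(design))
        return(mkPred("OK", wt = wt,
            detail = paste0(if (swapped) "forward/reverse roles swapped; " else "",
                            if (wt > param@maxAmplifiable && wt <= param@warnAmplifiable)
                                "wild-type product above the detectable ceiling but below the warn tier" else "")))

    if (as.character(seqnames(fSite)) != design@chrom)
        return(mkPred("OK", wt = wt,
            detail = "primers on a different chromosome than the deletion; wild-type size only"))

    delGenome <- deletionAllele(design, genome)
    delInt <- deletionInterval(design)
    lost <- character()
    for (side in c("forward", "reverse")) {
        site <- if (side == "forward") fSite else rSite
        if (start(site) <= end(delInt) && end(site) >= start(delInt))
            lost <- c(lost, side)
    }
    fDel <- uniqueSite(delGenome, forward)
    rDel <- uniqueSite(delGenome, reverse)
    if (length(lost) || identical(fDel, "unmapped") || identical(rDel, "unmapped"))
        return(mkPred("PrimerLost", wt = wt, detail = sprintf(
            "primer(s) lost to the deleted interval: %s",
            paste(if (length(lost)) lost else "junction-straddling", collapse = ", "))))
    if (identical(fDel, "ambiguous") || identical(rDel, "ambiguous"))
        return(mkPred("AmbiguousPrimer", wt = wt,
            detail = "primer maps more than once on the deletion allele"))
    if (swapped) { tmp <- fDel; fDel <- rDel; rDel <- tmp }
    if (!(as.character(strand(fDel)) == "+" && as.character(strand(rDel)) == "-") ||
        start(fDel) > start(rDel) ||
        as.character(seqnames(fDel)) != as.character(seqnames(rDel)))
        return(mkPred("Divergent", wt = wt,
            detail = "pair does not converge on the deletion allele"))
    del <- end(rDel) - start(fDel) + 1L
    notes <- character()
    if (swapped) notes <- c(notes, "forward/reverse roles swapped")
    if (wt > param@maxAmplifiable && wt <= param@warnAmplifiable)
        notes <- c(notes, "wild-type product above the detectable ceiling but below the warn tier")
    mkPred("OK", wt = wt, del = del, detail = paste(notes, collapse = "; "))
}

#' Nested-PCR consistency report
#'
#' Checks that the inner amplicon is strictly contained within the outer
#' amplicon on the reference and on the deletion allele, and reports all
#' four product sizes. Violations are reported (status
#' \code{InnerOutsideOuter}), not thrown, so whole primer panels can be
#' audited.
#'
#' @param outer,inner named lists or one-row data.frames with
#'   \code{name}, \code{forward}, \code{reverse}.
#' @param genome reference assembly.
#' @param design a \linkS4class{DeletionDesign} (or NULL for
#'   reference-only checks).
#' @param param a \linkS4class{GuideDesignParam}.
#' @return list with \code{status} (\code{OK} or \code{InnerOutsideOuter}
#'   or a primer failure), \code{outer} and \code{inner}
#'   \linkS4class{AmpliconPrediction}s, and logical
#'   \code{containedReference}/\code{containedDeletion}.
#' @export
nestedPlan <- function(outer, inner, genome, design = NULL,
                       param = GuideDesignParam()) {
    po <- predictAmplicon(outer$name, outer$forward, outer$reverse, genome,
                          design, param, tier = "OUTER")
    pin <- predictAmplicon(inner$name, inner$forward, inner$reverse, genome,
                          design, param, tier = "INNER")
    contained <- function(seqs) {
        oF <- uniqueSite(seqs, outer$forward); oR <- uniqueSite(seqs, outer$reverse)
        iF <- uniqueSite(seqs, inner$forward); iR <- uniqueSite(seqs, inner$reverse)
        if (!all(vapply(list(oF, oR, iF, iR), inherits, logical(1), "GRanges")))
            return(NA)
        span <- function(a, b) IRanges(min(start(a), start(b)), max(end(a), end(b)))
        so <- span(oF, oR); si <- span(iF, iR)
        start(si) > start(so) && end(si) < end(so)
    }
    cr <- contained(genome)
    cd <- if (is.null(design)) NA else contained(deletionAllele(design, genome))
    status <- if (po@status != "OK" || pin@status != "OK")
        "PrimerFailure"
    else if (isFALSE(cr) || isFALSE(cd))
        "InnerOutsideOuter"
    else "OK"
    list(status = status, outer = po, inner = pin,
         containedReference = cr, containedDeletion = cd)
}
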