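# plus-strand and reverse-complement strings per chromosome, computed once
genomeStrandCache <- function(genome) {
    setNames(lapply(names(genome), function(chrom) {
        rc <- reverseComplement(genome[[chrom]])
        list(fwd = as.character(genome[[chrom]]), rev = as.character(rc),
             fwdD = genome[[chrom]], revD = rc)
    }), names(genome))
}

# full footprint whose bases must be variant-free: protospacer plus PAM
guideFootprint <- function(guides) {
    fp <- footprintVectors(guides)
    GRanges(fp$chrom, IRanges(fp$s, fp$e), strand = "*")
}

# the same footprint as plain vectors (hot path)
footprintVectors <- function(guides) {
    m <- mcols(guides)
    list(chrom = as.character(seqnames(guides)),
         s = pmin(start(guides), m$pam_start),
         e = pmax(end(guides), m$pam_end))
}

#' Background variants overlapping guide candidates
#'
#' A guide is unusable when any SNP or indel from \emph{any} background
#' genome touches its protospacer or PAM: a single mismatch in the target -
#' above all in the 12-bp PAM-proximal core - can strongly reduce cutting,
#' and the same construct must work in every background it will be used in.
#' Variant records are compared in reference orientation; overlap, not
#' allele sequence, is the criterion, and insertions count via their anchor
#' base.
#'
#' @param guides guide \code{GRanges} from \code{\link{scanProtospacers}}.
#' @param variants a \code{GRanges} of variant records (see
#'   \code{\link{readVariants}}); several labelled sets may simply be
#'   concatenated.
#' @return a list, one element per guide: the subset of \code{variants}
#'   whose affected interval intersects that guide's protospacer-plus-PAM
#'   footprint.
#' @export
variantOverlaps <- function(guides, variants) {
    fp <- footprintVectors(guides)
    vChrom <- as.character(seqnames(variants))
    vS <- start(variants); vE <- end(variants)
    noHit <- variants[integer(0)]
    lapply(seq_along(fp$s), function(i) {
        if (length(variants) == 0L) return(variants)
        sel <- vChrom == fp$chrom[i] & vS <= fp$e[i] & vE >= fp$s[i]
        if (any(sel)) variants[sel] else noHit
    })
}

# scan one strand's worth of sequence (as a character scalar) for
# off-target sites of `proto` (20-nt guide-strand protospacer).
# Returns data.frame of hit starts (in the scanned orientation) + counts.
scanStrandOfftargets <- function(seqChar, proto, param, subject = NULL) {
    L <- nchar(seqChar)
    spacerLen <- nchar(proto)
    hits <- data.frame(s = integer(), mmTotal = integer(),
                       mmSeed = integer(), pamType = character())
    if (L < spacerLen + 3L) return(hits)
    seed <- substr(proto, 9L, 20L)
    if (param@maxMMSeed == 0L) {
        # exact seed: C-level regex with lookahead so overlapping
        # occurrences are not missed (seed is plain ACGT, no escaping)
        g <- gregexpr(paste0("(?=", seed, ")"), seqChar, perl = TRUE)[[1]]
        if (g[1L] == -1L) return(hits)
        seedStarts <- as.integer(g)
    } else {
        if (is.null(subject)) subject <- DNAString(seqChar)
        m <- matchPattern(DNAString(seed), subject,
                          max.mismatch = param@maxMMSeed, with.indels = FALSE)
        if (length(m) == 0L) return(hits)
        seedStarts <- start(m)
    }
    starts <- seedStarts - 8L              # protospacer start
    starts <- starts[starts >= 1L & starts + spacerLen + 2L <= L]
    if (length(starts) == 0L) return(hits)
    protoV <- strsplit(proto, "", fixed = TRUE)[[1]]
    keepS <- integer(); keepT <- integer(); keepSd <- integer(); keepP <- character()
    for (s in starts) {
        pam23 <- substr(seqChar, s + spacerLen + 1L, s + spacerLen + 2L)
        pamType <- if (pam23 == "GG") "NGG" else if (pam23 == "AG") "NAG" else NA_character_
        if (is.na(pamType) || !pamType %in% param@offtargetPAMs) next
        site <- strsplit(substr(seqChar, s, s + spacerLen - 1L), "", fixed = TRUE)[[1]]
        mm <- site != protoV               # N in the genome counts as mismatch
        mmTotal <- sum(mm)
        if (mmTotal > param@maxMMTotal) next
        mmSeed <- sum(mm[9:20])
        if (mmSeed > param@maxMMSeed) next
        keepS <- c(keepS, s); keepT <- c(keepT, mmTotal)
        keepSd <- c(keepSd, mmSeed); keepP <- c(keepP, pamType)
    }
    data.frame(s = keepS, mmTotal = keepT, mmSeed = keepSd, pamType = keepP,
               stringsAsFactors = FALSE)
}

#' Enumerate predicted off-targets of one guide candidate
#'
#' Finds every genomic site, on either strand of any chromosome, whose
#' protospacer alignment to the candidate has at most \code{maxMMSeed}
#' mismatches in the 12-nt PAM-proximal seed (default 0) and at most
#' \code{maxMMTotal} mismatches overall (default 3), adjacent to an
#' admitted PAM (default NGG and NAG; the N is a wildcard and PAM bases are
#' never counted as mismatches). The on-target locus itself is excluded.
#' The search is exact at this tool's intended genome scale - the seed
#' match is delegated to \code{Biostrings} pattern matching and every seed
#' hit is then verified base by base, so there are no heuristic misses.
#'
#' @param guide a length-1 guide \code{GRanges}
#'   (from \code{\link{scanProtospacers}}).
#' @param genome the assembly \code{DNAStringSet}.
#' @param param a \linkS4class{GuideDesignParam}.
#' @param strandCache optional precomputed per-chromosome plus-strand and
#'   reverse-complement strings (built internally when screening many
#'   guides against the same assembly).
#' @return \code{GRanges} of off-target protospacer sites with metadata
#'   columns \code{pam_type}, \code{mm_total}, \code{mm_seed}.
#' @export
findOfftargets <- function(guide, genome, param = GuideDesignParam(),
                           strandCache = NULL) {
    stopifnot(length(guide) == 1L)
    h <- offtargetHitsCore(mcols(guide)$protospacer,
                           as.character(seqnames(guide)),
                           as.character(strand(guide)), start(guide),
                           genome, param, strandCache)
    gr <- GRanges(h$chrom, IRanges(h$start, width = nchar(mcols(guide)$protospacer)),
                  strand = h$strand)
    mcols(gr) <- DataFrame(pam_type = h$pam_type, mm_total = h$mm_total,
                           mm_seed = h$mm_seed)
    if (length(gr) > 1L) gr <- sort(gr, ignore.strand = TRUE)
    gr
}

# plain-vector core of the off-target search (no S4 per-hit overhead)
offtargetHitsCore <- function(proto, onChrom, onStrand, onStart, genome,
                              param, strandCache = NULL) {
    spacerLen <- nchar(proto)
    if (is.null(strandCache)) strandCache <- genomeStrandCache(genome)
    empty <- data.frame(chrom = character(), strand = character(),
                        start = integer(), pam_type = character(),
                        mm_total = integer(), mm_seed = integer(),
                        stringsAsFactors = FALSE)
    out <- list(empty)
    for (chrom in names(genome)) {
        L <- nchar(strandCache[[chrom]]$fwd)
        h <- scanStrandOfftargets(strandCache[[chrom]]$fwd, proto, param,
                                  strandCache[[chrom]]$fwdD)
        if (nrow(h)) {
            keep <- !(chrom == onChrom & onStrand == "+" & h$s == onStart)
            h <- h[keep, , drop = FALSE]
            if (nrow(h))
                out[[length(out) + 1L]] <- data.frame(chrom = chrom,
                    strand = "+", start = h$s, pam_type = h$pamType,
                    mm_total = h$mmTotal, mm_seed = h$mmSeed,
                    stringsAsFactors = FALSE)
        }
        h <- scanStrandOfftargets(strandCache[[chrom]]$rev, proto, param,
                                  strandCache[[chrom]]$revD)
        if (nrow(h)) {
            refStart <- L - (h$s + spacerLen - 1L) + 1L
            keep <- !(chrom == onChrom & onStrand == "-" & refStart == onStart)
            h <- h[keep, , drop = FALSE]
            refStart <- refStart[keep]
            if (nrow(h))
                out[[length(out) + 1L]] <- data.frame(chrom = chrom,
                    strand = "-", start = refStart, pam_type = h$pamType,
                    mm_total = h$mmTotal, mm_seed = h$mmSeed,
                    stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}

#' Position-weight efficiency score
#'
#' Scores protospacers with an additive position-weight model: the raw
#' score is the sum over protospacer positions 1-20 of the weight of the
#' observed base, affinely rescaled to [0, 10] using the table's own
#' attainable minimum and maximum (a degenerate all-equal table maps every
#' guide to the midpoint 5). The default table is
#' \code{\link{defaultEfficiencyWeights}}; any complete 4 x 20 matrix may
#' be supplied, so externally trained models plug in unchanged.
#'
#' @param guides guide \code{GRanges} or character vector of 20-nt
#'   protospacers.
#' @param weights 4 x 20 numeric matrix, rows named A, C, G, T.
#' @return numeric vector of scores in [0, 10].
#' @examples
#' efficiencyScore(c("GGGGGGGGGGGGGGGGGGGG", "TTTTTTTTTTTTTTTTTTTT"))
#' @export
efficiencyScore <- function(guides, weights = defaultEfficiencyWeights()) {
    proto <- if (is.character(guides)) guides else mcols(guides)$protospacer
    stopifnot(all(nchar(proto) == ncol(weights)))
    if (!identical(rownames(weights), c("A", "C", "G", "T")) ||
        any(is.na(weights)))
        stopInputError("InputError",
            "weight table must be a complete matrix with rows A, C, G, T")
    lo <- sum(apply(weights, 2L, min)); hi <- sum(apply(weights, 2L, max))
    raw <- vapply(proto, function(p) {
        b <- strsplit(p, "", fixed = TRUE)[[1]]
        if (!all(b %in% rownames(weights)))
            stopInputError("InputError",
                sprintf("protospacer '%s' contains a base with no table entry", p))
        sum(weights[cbind(match(b, rownames(weights)), seq_along(b))])
    }, numeric(1), USE.NAMES = FALSE)
    if (hi == lo) rep(5, length(raw)) else 10 * (raw - lo) / (hi - lo)
}

#' Screen guide candidates
#'
#' Composes the three screens - background-variant overlap, off-target
#' enumeration and efficiency scoring - into one verdict per candidate.
#' All three are always evaluated (no short-circuiting) so audit reports
#' are complete. The verdict is \code{PASS} iff there are zero variant hits
#' in every background, zero predicted off-targets, and the efficiency
#' score reaches the configured floor; otherwise the dominant failure is
#' reported as \code{FAIL_VARIANT}, \code{FAIL_OFFTARGET} or
#' \code{FAIL_EFFICIENCY} (in that precedence).
#'
#' @param guides guide \code{GRanges} from \code{\link{scanProtospacers}}.
#' @param genome the assembly \code{DNAStringSet}.
#' @param variants \code{GRanges} of labelled background variants (may be
#'   empty).
#' @param param a \linkS4class{GuideDesignParam}.
#' @return a \code{DataFrame}, one row per guide, with columns
#'   \code{protospacer}, \code{efficiency}, \code{nVariantHits},
#'   \code{nOfftargets}, \code{verdict}; per-guide hit details are in
#'   \code{metadata(x)$variantHits} (variant \code{GRanges} subsets) and
#'   \code{metadata(x)$offtargets} (data.frames as from
#'   \code{\link{bruteForceOfftargets}}).
#' @export
screenGuides <- function(guides, genome, variants = GRanges(),
                         param = GuideDesignParam()) {
    n <- length(guides)
    vh <- variantOverlaps(guides, variants)
    sc <- genomeStrandCache(genome)
    protos <- mcols(guides)$protospacer
    gChrom <- as.character(seqnames(guides))
    gStrand <- as.character(strand(guides))
    gStart <- start(guides)
    ot <- lapply(seq_len(n), function(i)
        offtargetHitsCore(protos[i], gChrom[i], gStrand[i], gStart[i],
                          genome, param, strandCache = sc))
    eff <- if (n) efficiencyScore(guides, param@efficiencyWeights) else numeric()
    nvh <- vapply(vh, length, integer(1))
    not <- vapply(ot, nrow, integer(1))
    verdict <- ifelse(nvh > 0L, "FAIL_VARIANT",
               ifelse(not > 0L, "FAIL_OFFTARGET",
               ifelse(eff < param@efficiencyFloor, "FAIL_EFFICIENCY", "PASS")))
    res <- DataFrame(protospacer = if (n) mcols(guides)$protospacer else character(),
                     efficiency = eff,
                     nVariantHits = nvh,
                     nOfftargets = not,
                     verdict = as.character(verdict))
    metadata(res)$variantHits <- vh
    metadata(res)$offtargets <- ot
    metadata(res)$param <- paramAsList(param)
    res
}
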