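# ---------------------------------------------------------------------------
# Deterministic synthetic fixtures with oracle-verified ground truth.
#
# Everything in this file that is called oracle* is an intentionally naive,
# loop/regex/raw-vector implementation of the documented design rules,
# independent of the GRanges/Biostrings pipeline it is used to check.
# ---------------------------------------------------------------------------

BASES <- c("A", "C", "G", "T")

# per-chromosome character vectors (plus strand and reverse complement),
# computed once and reused across repeated brute-force scans
genomeCharCache <- function(genome) {
    setNames(lapply(names(genome), function(chrom) {
        fwd <- strsplit(as.character(genome[[chrom]]), "", fixed = TRUE)[[1]]
        list(fwd = fwd, rev = rev(chartr("ACGTN", "TGCAN", fwd)))
    }), names(genome))
}

randSeq <- function(n, gc = 0.43) {
    paste(sample(BASES, n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

# --- naive oracles ---------------------------------------------------------

# brute-force all-positions off-target enumeration over raw character
# vectors; the reference implementation against which findOfftargets is
# verified. Exported because it is also the audit tool's second opinion.

#' Brute-force off-target enumeration (reference implementation)
#'
#' Enumerates off-target sites of a 20-nt protospacer by sliding over every
#' position of every chromosome on both strands and counting mismatches
#' directly on character vectors - no pattern-matching shortcuts. Slow but
#' transparently correct; used to cross-check
#' \code{\link{findOfftargets}}, which must agree exactly.
#'
#' @param proto 20-nt protospacer (guide strand, 5'->3').
#' @param genome \code{DNAStringSet}.
#' @param param \linkS4class{GuideDesignParam} (off-target knobs used).
#' @param onTarget optional list(chrom, strand, start) of the on-target
#'   protospacer site to exclude.
#' @param seqCache optional precomputed character-vector cache from
#'   \code{genomeCharCache} (internal speed-up for repeated scans).
#' @return data.frame with columns chrom, strand, start (reference
#'   protospacer start), pam_type, mm_total, mm_seed.
#' @export
bruteForceOfftargets <- function(proto, genome, param = GuideDesignParam(),
                                 onTarget = NULL, seqCache = NULL) {
    patV <- strsplit(proto, "", fixed = TRUE)[[1]]
    k <- length(patV)
    res <- list()
    useNGG <- "NGG" %in% param@offtargetPAMs
    useNAG <- "NAG" %in% param@offtargetPAMs
    scanOne <- function(cv, chrom, strandCh, L) {
        n <- length(cv) - k - 2L
        if (n < 1L) return()
        # admissible PAM positions first (N is a wildcard)
        b2 <- cv[seq_len(n) + k + 1L]; b3 <- cv[seq_len(n) + k + 2L]
        pam <- rep(NA_character_, n)
        g3 <- b3 == "G"
        if (useNGG) pam[g3 & b2 == "G"] <- "NGG"
        if (useNAG) pam[g3 & b2 == "A"] <- "NAG"
        cand <- which(!is.na(pam))
        if (length(cand) == 0L) return()
        mmTot <- integer(length(cand)); mmSeed <- integer(length(cand))
        for (j in seq_len(k)) {
            neq <- cv[cand + j - 1L] != patV[j]
            mmTot <- mmTot + neq
            if (j >= 9L) mmSeed <- mmSeed + neq
        }
        keep <- mmTot <= param@maxMMTotal & mmSeed <= param@maxMMSeed
        if (!any(keep)) return()
        s <- cand[keep]
        refStart <- if (strandCh == "+") s else L - (s + k - 1L) + 1L
        df <- data.frame(chrom = chrom, strand = strandCh, start = refStart,
                         pam_type = pam[cand][keep], mm_total = mmTot[keep],
                         mm_seed = mmSeed[keep], stringsAsFactors = FALSE)
        res[[length(res) + 1L]] <<- df
    }
    if (is.null(seqCache)) seqCache <- genomeCharCache(genome)
    for (chrom in names(genome)) {
        L <- length(genome[[chrom]])
        scanOne(seqCache[[chrom]]$fwd, chrom, "+", L)
        scanOne(seqCache[[chrom]]$rev, chrom, "-", L)
    }
    if (length(res) == 0L)
        return(data.frame(chrom = character(), strand = character(),
                          start = integer(), pam_type = character(),
                          mm_total = integer(), mm_seed = integer(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, res)
    if (!is.null(onTarget))
        out <- out[!(out$chrom == onTarget$chrom &
                     out$strand == onTarget$strand &
                     out$start == onTarget$start), , drop = FALSE]
    out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# naive region selection: logical foreign-CDS mask + explicit position loops
oracleRegions <- function(gene, genome, allGenes, param) {
    chromStr <- as.character(genome[[gene@chrom]])
    L <- nchar(chromStr)
    mask <- logical(L)
    for (g in allGenes) {
        if (geneID(g) == geneID(gene) || g@chrom != gene@chrom) next
        for (tx in as.list(transcripts(g)))
            for (i in seq_along(tx)) mask[start(tx)[i]:end(tx)[i]] <- TRUE
    }
    plus <- gene@geneStrand == "+"
    txl <- transcripts(gene)
    allS <- unlist(lapply(as.list(txl), start))
    allE <- unlist(lapply(as.list(txl), end))
    ancStart <- if (plus) min(allS) else max(allE)
    ancStop  <- if (plus) max(allE) else min(allS)

    pickExon <- function(pos) {
        best <- NULL
        for (tn in names(txl)) {
            tx <- txl[[tn]]
            for (i in seq_along(tx)) {
                if (start(tx)[i] <= pos && end(tx)[i] >= pos) {
                    w <- end(tx)[i] - start(tx)[i] + 1L
                    if (is.null(best) || w > best$w ||
                        (w == best$w && start(tx)[i] < best$s))
                        best <- list(tn = tn, i = i, w = w, s = start(tx)[i])
                }
            }
        }
        best
    }
    W <- param@windowLength; Wmin <- param@minWindow
    oneRole <- function(role) {
        pos <- if (role == "START") ancStart else ancStop
        px <- pickExon(pos)
        if (is.null(px)) return(list(fail = "InputError"))
        tx <- txl[[px$tn]]
        interiorRight <- (role == "START") == plus
        order_ <- if (interiorRight) px$i:length(tx) else px$i:1
        for (ki in seq_along(order_)) {
            k <- order_[ki]
            es <- start(tx)[k]; ee <- end(tx)[k]
            if (ee - es + 1L < Wmin) next
            anchored <- ki == 1L
            if (interiorRight) {
                s0 <- if (anchored) pos else es
                if (s0 > ee - Wmin + 1L) next
                for (s in s0:(ee - Wmin + 1L)) {
                    e <- min(s + W - 1L, ee)
                    if (!any(mask[s:e]))
                        return(list(s = s, e = e,
                                    shifted = !(anchored && s == pos)))
                }
            } else {
                e0 <- if (anchored) pos else ee
                if (e0 < es + Wmin - 1L) next
                for (e in e0:(es + Wmin - 1L)) {
                    s <- max(e - W + 1L, es)
                    if (!any(mask[s:e]))
                        return(list(s = s, e = e,
                                    shifted = !(anchored && e == pos)))
                }
            }
        }
        list(fail = "NoCleanRegion")
    }
    list(START = oneRole("START"), STOP = oneRole("STOP"),
         anchors = c(start = ancStart, stop = ancStop))
}

# naive protospacer enumeration in [rs, re] via substring checks
oracleScanGuides <- function(chromStr, rs, re, param) {
    L <- nchar(chromStr)
    slack <- param@pamSlack; k <- param@spacerLength
    out <- list()
    sub <- function(a, b) substr(chromStr, a, b)
    for (q in seq_len(L)) {                   # q = PAM start, plus strand
        if (q - k < rs || q - 1L > re) next
        if (q + 2L > min(L, re + slack)) next
        if (sub(q + 1L, q + 2L) != "GG") next
        proto <- sub(q - k, q - 1L)
        if (grepl("N", proto, fixed = TRUE) || grepl("N", sub(q, q + 2L), fixed = TRUE)) next
        out[[length(out) + 1L]] <- list(strand = "+", start = q - k,
                                        proto = proto, cut = q - 4L)
    }
    for (q in seq_len(L)) {                   # q = PAM start (ref CCN), minus
        if (q + 3L < rs || q + k + 2L > re) next
        if (q < max(1L, rs - slack)) next
        if (sub(q, q + 1L) != "CC") next
        protoRef <- sub(q + 3L, q + k + 2L)
        if (grepl("N", protoRef, fixed = TRUE) || grepl("N", sub(q, q + 2L), fixed = TRUE)) next
        out[[length(out) + 1L]] <- list(strand = "-", start = q + 3L,
                                        proto = revcompChr(protoRef),
                                        cut = q + 5L)
    }
    out
}

# independent recomputation of the position-weight score
oracleEfficiency <- function(proto, weights) {
    lo <- 0; hi <- 0
    for (j in seq_len(ncol(weights))) {
        lo <- lo + min(weights[, j]); hi <- hi + max(weights[, j])
    }
    raw <- 0
    b <- strsplit(proto, "", fixed = TRUE)[[1]]
    for (j in seq_along(b)) raw <- raw + weights[b[j], j]
    if (hi == lo) 5 else 10 * (raw - lo) / (hi - lo)
}

# naive variant-overlap check against a plain data.frame of variants
oracleVariantHit <- function(chrom, fpStart, fpEnd, vdf) {
    any(vdf$chrom == chrom & vdf$start <= fpEnd & vdf$end >= fpStart)
}

# full naive pipeline for one gene: documented ranking over the PASS x PASS
# grid. Returns either list(design = ...) or list(fail = class, stage =)
oracleDesign <- function(gene, genome, allGenes, vdf, param) {
    reg <- oracleRegions(gene, genome, allGenes, param)
    if (!is.null(reg$START$fail))
        return(list(fail = reg$START$fail, stage = "regions"))
    if (!is.null(reg$STOP$fail))
        return(list(fail = reg$STOP$fail, stage = "regions"))
    chromStr <- as.character(genome[[gene@chrom]])
    cache <- genomeCharCache(genome)
    screenSide <- function(r, role) {
        cands <- oracleScanGuides(chromStr, r$s, r$e, param)
        if (length(cands) == 0L) return(NULL)
        keep <- list()
        for (cd in cands) {
            k <- param@spacerLength
            fpS <- if (cd$strand == "+") cd$start else cd$start - 3L
            fpE <- if (cd$strand == "+") cd$start + k - 1L + 3L else cd$start + k - 1L
            if (oracleVariantHit(gene@chrom, fpS, fpE, vdf)) next
            ot <- bruteForceOfftargets(cd$proto, genome, param,
                onTarget = list(chrom = gene@chrom, strand = cd$strand,
                                start = cd$start), seqCache = cache)
            if (nrow(ot) > 0L) next
            eff <- oracleEfficiency(cd$proto, param@efficiencyWeights)
            if (eff < param@efficiencyFloor) next
            adj <- sum(vdf$chrom == gene@chrom &
                       vdf$start <= fpE + 10L & vdf$end >= fpS - 10L)
            keep[[length(keep) + 1L]] <- c(cd, list(eff = eff, adj = adj,
                                                    role = role))
        }
        keep
    }
    pStart <- screenSide(reg$START, "START")
    pStop <- screenSide(reg$STOP, "STOP")
    if (is.null(pStart) || length(pStart) == 0L ||
        is.null(pStop) || length(pStop) == 0L)
        return(list(fail = "NoViablePair", stage = "screening",
                    regions = reg))
    best <- NULL
    for (a in pStart) for (b in pStop) {
        sep <- abs(b$cut - a$cut)
        if (sep < param@minSeparation) next
        key <- list(eff = round(a$eff + b$eff, 9L), c1 = a$cut, c2 = b$cut)
        if (is.null(best) || key$eff > best$key$eff ||
            (key$eff == best$key$eff &&
             (key$c1 < best$key$c1 ||
              (key$c1 == best$key$c1 && key$c2 < best$key$c2))))
            best <- list(a = a, b = b, key = key)
    }
    if (is.null(best))
        return(list(fail = "NoViablePair", stage = "pairing", regions = reg))
    list(regions = reg,
         design = list(proto_start = best$a$proto, proto_stop = best$b$proto,
                       cut1 = min(best$a$cut, best$b$cut),
                       cut2 = max(best$a$cut, best$b$cut),
                       size = abs(best$b$cut - best$a$cut)))
}

# exact-occurrence count of a short string and its revcomp in the genome
countHits <- function(genome, s) {
    tot <- 0L
    for (chrom in names(genome)) {
        cs <- as.character(genome[[chrom]])
        for (pat in unique(c(s, revcompChr(s)))) {
            g <- gregexpr(pat, cs, fixed = TRUE)[[1]]
            tot <- tot + sum(g != -1L)
        }
    }
    tot
}

# --- gene construction -----------------------------------------------------

# build the sense sequence of one locus and the exon layout (sense coords)
buildLocusSense <- function(nExons, gc, intron1Min = 45L, intron1Max = 140L) {
    exLen <- integer(nExons)
    for (i in seq_len(nExons)) {
        exLen[i] <- if (i == 1L || i == nExons) sample(130:200, 1L)
                    else sample(60:160, 1L)
    }
    if (nExons == 1L) exLen[1L] <- sample(c(150L, sample(500:800, 1L)), 1L)
    # CDS length divisible by 3
    rem <- sum(exLen) %% 3L
    if (rem) exLen[nExons] <- exLen[nExons] + (3L - rem)
    inLen <- if (nExons > 1L)
        c(sample(intron1Min:intron1Max, 1L),
          if (nExons > 2L) sample(45:140, nExons - 2L, replace = TRUE))
    else integer()
    pieces <- character(); exS <- integer(); exE <- integer(); pos <- 0L
    for (i in seq_len(nExons)) {
        ex <- randSeq(exLen[i], gc)
        if (i == 1L) substr(ex, 1L, 3L) <- "ATG"
        if (i == nExons) substr(ex, exLen[i] - 2L, exLen[i]) <- "TAA"
        pieces <- c(pieces, ex)
        exS <- c(exS, pos + 1L); exE <- c(exE, pos + exLen[i])
        pos <- pos + exLen[i]
        if (i < nExons) {
            intr <- randSeq(inLen[i], gc)
            substr(intr, 1L, 2L) <- "GT"
            substr(intr, inLen[i] - 1L, inLen[i]) <- "AG"
            pieces <- c(pieces, intr)
            pos <- pos + inLen[i]
        }
    }
    list(seq = paste(pieces, collapse = ""), exS = exS, exE = exE,
         len = pos)
}

# map sense-coordinate exons to genomic coordinates for a locus planted at
# offset g0 (1-based genome position of the locus' first base)
senseToGenomic <- function(locus, g0, strandCh) {
    M <- locus$len
    if (strandCh == "+")
        list(s = g0 + locus$exS - 1L, e = g0 + locus$exE - 1L,
             seq = locus$seq)
    else
        list(s = g0 + (M - locus$exE), e = g0 + (M - locus$exS),
             seq = revcompChr(locus$seq))
}

# --- variant planting ------------------------------------------------------

otherBase <- function(b) sample(setdiff(BASES, b), 1L)

# draw random SNP/indel records over [lo, hi]; returns a data.frame in
# reference coordinates (chrom, start, end, ref, alt, type, label)
drawVariants <- function(chromStr, chrom, lo, hi, density, label,
                         indelFrac = 0.15) {
    span <- hi - lo + 1L
    n <- min(stats::rbinom(1L, span, density), (span - 4L) %/% 2L)
    if (n <= 0L)
        return(data.frame(chrom = character(), start = integer(),
                          end = integer(), ref = character(),
                          alt = character(), type = character(),
                          label = character(), stringsAsFactors = FALSE))
    pos <- sort(sample(lo:(hi - 4L), n, replace = FALSE))
    rows <- list()
    lastEnd <- 0L
    for (p in pos) {
        if (p <= lastEnd) next                 # keep records non-overlapping
        roll <- stats::runif(1L)
        refBase <- substr(chromStr, p, p)
        if (roll > indelFrac) {
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = chrom, start = p, end = p, ref = refBase,
                alt = otherBase(refBase), type = "SNP", label = label,
                stringsAsFactors = FALSE)
            lastEnd <- p
        } else if (roll > indelFrac / 2) {
            ins <- randSeq(sample(1:4, 1L))
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = chrom, start = p, end = p, ref = refBase,
                alt = paste0(refBase, ins), type = "INS", label = label,
                stringsAsFactors = FALSE)
            lastEnd <- p
        } else {
            dlen <- sample(1:4, 1L)
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = chrom, start = p, end = p + dlen,
                ref = substr(chromStr, p, p + dlen),
                alt = refBase, type = "DEL", label = label,
                stringsAsFactors = FALSE)
            lastEnd <- p + dlen
        }
    }
    do.call(rbind, rows)
}

variantsToGRanges <- function(vdf) {
    if (is.null(vdf) || nrow(vdf) == 0L) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(ref = character(), alt = character(),
                               type = character(), label = character())
        return(gr)
    }
    gr <- GRanges(vdf$chrom, IRanges(vdf$start, vdf$end), strand = "*")
    mcols(gr) <- DataFrame(ref = vdf$ref, alt = vdf$alt, type = vdf$type,
                           label = vdf$label)
    gr
}

# --- the bundle generator --------------------------------------------------

FIXTURE_DIFFICULTIES <- c("CLEAN", "NESTED_ORF", "MULTI_ISOFORM",
                          "SNP_DENSE", "OFFTARGET_TRAP", "SINGLE_EXON")

#' Generate a synthetic fixture bundle with oracle-verified ground truth
#'
#' Builds, deterministically from a seed, a random genome with planted gene
#' models, two labelled background variant sets (emulating a cell-line and
#' an injection-stock background), difficulty-specific hazards, and - when
#' the gene is designable - a planted diagnostic primer pair. The expected
#' outcome of the whole design pipeline (target regions, chosen guide pair,
#' deletion size, amplicon sizes, or the expected failure) is computed at
#' generation time by this module's naive brute-force oracles and stored in
#' the bundle's \code{truth} slot.
#'
#' Difficulties plant specific hazards: \code{NESTED_ORF} a foreign CDS
#' overlapping the host's first coding exon and first intron (forcing the
#' START region onto a later exon); \code{MULTI_ISOFORM} up to four splice
#' forms with distinct start/stop codons; \code{SNP_DENSE} a dense SNP/indel
#' background; \code{OFFTARGET_TRAP} seed-exact near-duplicates of real
#' candidates planted in intergenic space; \code{SINGLE_EXON} a one-exon
#' gene that may be too short for the minimum cut separation; \code{CLEAN}
#' none of these (background variants are kept clear of the target regions).
#'
#' @param seed integer; same seed, same bundle, byte for byte.
#' @param difficulty one of \code{CLEAN}, \code{NESTED_ORF},
#'   \code{MULTI_ISOFORM}, \code{SNP_DENSE}, \code{OFFTARGET_TRAP},
#'   \code{SINGLE_EXON}.
#' @param genomeLength total assembly length, 10000-200000 bp.
#' @param nGenes number of planted genes (1-3).
#' @param snpDensity per-base variant rate for the backgrounds, 0-0.01;
#'   default depends on difficulty.
#' @param gc GC content of random sequence (default 0.43, fly-like).
#' @param param \linkS4class{GuideDesignParam} under which the ground truth
#'   is computed.
#' @return a \linkS4class{FixtureBundle}.
#' @examples
#' b <- makeBundle(1, "CLEAN", genomeLength = 12000)
#' b
#' @export
makeBundle <- function(seed, difficulty = "CLEAN", genomeLength = 20000L,
                       nGenes = 1L, snpDensity = NULL, gc = 0.43,
                       param = GuideDesignParam()) {
    difficulty <- match.arg(difficulty, FIXTURE_DIFFICULTIES)
    genomeLength <- as.integer(genomeLength)
    if (genomeLength < 10000L || genomeLength > 200000L)
        stopInputError("InputError", "genomeLength must be in [10000, 200000]")
    if (nGenes < 1L || nGenes > 3L)
        stopInputError("InputError", "nGenes must be 1-3")
    if (is.null(snpDensity))
        snpDensity <- switch(difficulty, SNP_DENSE = 0.004, CLEAN = 0, 0.0008)
    if (snpDensity < 0 || snpDensity > 0.01)
        stopInputError("InputError", "snpDensity must be in [0, 0.01]")

    if (exists(".Random.seed", envir = globalenv())) {
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    }
    set.seed(seed)
    chrom <- "chrF"

    # --- plan loci
    loci <- list()
    for (gidx in seq_len(nGenes)) {
        nEx <- switch(difficulty,
            SINGLE_EXON = 1L,
            NESTED_ORF = sample(3:4, 1L),
            MULTI_ISOFORM = sample(3:4, 1L),
            sample(2:4, 1L))
        i1min <- if (difficulty == "NESTED_ORF") 260L else 45L
        i1max <- if (difficulty == "NESTED_ORF") 400L else 140L
        loci[[gidx]] <- buildLocusSense(nEx, gc, i1min, i1max)
    }
    trapPad <- 320L
    minPad <- 300L
    need <- sum(vapply(loci, `[[`, integer(1), "len")) +
        (nGenes + 1L) * minPad + trapPad
    if (need > genomeLength)
        stopInputError("InputError",
            sprintf("planted genes (%d bp with pads) exceed genomeLength %d",
                    need, genomeLength))
    spare <- genomeLength - need
    extra <- if (nGenes + 1L > 1L) {
        cuts <- sort(sample(0:spare, nGenes, replace = TRUE))
        diff(c(0L, cuts, spare))
    } else spare
    padLen <- minPad + extra[seq_len(nGenes + 1L)]

    # --- assemble sequence and gene models
    pieces <- character(); genes <- list(); pos <- 0L
    geneStrands <- sample(c("+", "-"), nGenes, replace = TRUE)
    for (gidx in seq_len(nGenes)) {
        pieces <- c(pieces, randSeq(padLen[gidx], gc)); pos <- pos + padLen[gidx]
        g0 <- pos + 1L
        gmap <- senseToGenomic(loci[[gidx]], g0, geneStrands[gidx])
        pieces <- c(pieces, gmap$seq); pos <- pos + loci[[gidx]]$len
        gid <- sprintf("gene%02d", gidx)
        exGR <- GRanges(chrom, IRanges(sort(gmap$s), sort(gmap$e)))
        txl <- list(exGR)
        if (difficulty == "MULTI_ISOFORM" && length(exGR) >= 2L) {
            # alternative starts: drop leading exon(s); trim within an exon
            txl <- c(txl, list(exGR[-1L]))
            if (length(exGR) >= 3L) txl <- c(txl, list(exGR[-(1:2)]))
            tr <- exGR
            if (geneStrands[gidx] == "+") {
                start(tr)[1L] <- start(tr)[1L] + 21L
                end(tr)[length(tr)] <- end(tr)[length(tr)] - 15L
            } else {
                end(tr)[length(tr)] <- end(tr)[length(tr)] - 21L
                start(tr)[1L] <- start(tr)[1L] + 15L
            }
            txl <- c(txl, list(tr))
        }
        genes[[gid]] <- GeneModel(gid, chrom, geneStrands[gidx], txl)
    }
    pieces <- c(pieces, randSeq(padLen[nGenes + 1L] + trapPad, gc))
    pos <- pos + padLen[nGenes + 1L] + trapPad
    chromStr <- paste(pieces, collapse = "")
    stopifnot(nchar(chromStr) == genomeLength)

    # --- NESTED_ORF: foreign CDS over exon 1 of gene 1 (annotation only)
    if (difficulty == "NESTED_ORF") {
        host <- genes[[1L]]
        hostTx <- transcripts(host)[[1L]]
        firstEx <- if (host@geneStrand == "+") hostTx[1L]
                   else hostTx[length(hostTx)]
        intoIntron <- 120L
        fs <- max(1L, start(firstEx) - 15L)
        fe <- min(genomeLength, end(firstEx) + intoIntron)
        if (host@geneStrand == "-") {
            fs <- max(1L, start(firstEx) - intoIntron)
            fe <- min(genomeLength, end(firstEx) + 15L)
        }
        foreignStrand <- if (host@geneStrand == "+") "-" else "+"
        genes[["nested01"]] <- GeneModel("nested01", chrom, foreignStrand,
            list(GRanges(chrom, IRanges(fs, fe))))
    }

    genome <- DNAStringSet(setNames(chromStr, chrom))

    # --- OFFTARGET_TRAP: plant seed-exact near-duplicates in the trap pad
    if (difficulty == "OFFTARGET_TRAP") {
        reg <- oracleRegions(genes[[1L]], genome, genes, param)
        if (is.null(reg$START$fail) && is.null(reg$STOP$fail)) {
            trapStart <- genomeLength - trapPad + 10L
            off <- 0L
            for (side in list(reg$START, reg$STOP)) {
                cands <- oracleScanGuides(chromStr, side$s, side$e, param)
                if (length(cands) == 0L) next
                pickN <- max(1L, length(cands) %/% 2L)
                for (cd in cands[sample.int(length(cands), pickN)]) {
                    site <- cd$proto
                    nmm <- sample(0:2, 1L)
                    if (nmm > 0L) {
                        mmAt <- sample(1:8, nmm)   # outside the 12-nt seed
                        for (j in mmAt)
                            substr(site, j, j) <- otherBase(substr(site, j, j))
                    }
                    pam <- paste0(sample(BASES, 1L),
                                  sample(c("GG", "AG"), 1L, prob = c(0.7, 0.3)))
                    planted <- paste0(site, pam)
                    p0 <- trapStart + off
                    if (p0 + nchar(planted) - 1L > genomeLength) break
                    substr(chromStr, p0, p0 + nchar(planted) - 1L) <- planted
                    off <- off + nchar(planted) + 5L
                }
            }
            genome <- DNAStringSet(setNames(chromStr, chrom))
        }
    }

    # --- background variants (two labels)
    labels <- c("S2Rplus", "attP40")
    vdfs <- list()
    if (snpDensity > 0) {
        for (lab in labels) {
            for (gidx in seq_len(nGenes)) {
                g <- genes[[sprintf("gene%02d", gidx)]]
                cds <- unlist(transcripts(g))
                lo <- max(6L, min(start(cds)) - 200L)
                hi <- min(genomeLength - 6L, max(end(cds)) + 200L)
                vdfs[[length(vdfs) + 1L]] <-
                    drawVariants(chromStr, chrom, lo, hi, snpDensity, lab)
            }
        }
    } else {
        # CLEAN: a handful of variants well away from every target region
        exclude <- IRanges()
        for (gid in names(genes)) {
            reg <- oracleRegions(genes[[gid]], genome, genes, param)
            if (is.null(reg$START$fail))
                exclude <- c(exclude, IRanges(reg$START$s - 30L, reg$START$e + 30L))
            if (is.null(reg$STOP$fail))
                exclude <- c(exclude, IRanges(reg$STOP$s - 30L, reg$STOP$e + 30L))
        }
        for (lab in labels) {
            got <- 0L; rows <- list(); tries <- 0L
            while (got < 4L && tries < 200L) {
                tries <- tries + 1L
                p <- sample(10:(genomeLength - 10L), 1L)
                if (length(exclude) && any(start(exclude) <= p & end(exclude) >= p)) next
                refBase <- substr(chromStr, p, p)
                rows[[length(rows) + 1L]] <- data.frame(
                    chrom = chrom, start = p, end = p, ref = refBase,
                    alt = otherBase(refBase), type = "SNP", label = lab,
                    stringsAsFactors = FALSE)
                got <- got + 1L
            }
            vdfs[[length(vdfs) + 1L]] <- do.call(rbind, rows)
        }
    }
    vdf <- do.call(rbind, c(vdfs, list(data.frame(
        chrom = character(), start = integer(), end = integer(),
        ref = character(), alt = character(), type = character(),
        label = character(), stringsAsFactors = FALSE))))
    vdf <- vdf[order(vdf$start, vdf$label), , drop = FALSE]
    rownames(vdf) <- NULL

    # --- ground truth via the naive oracles
    truth <- list(seed = seed, difficulty = difficulty, genes = list())
    for (gid in names(genes)) {
        if (grepl("^nested", gid)) next
        res <- oracleDesign(genes[[gid]], genome, genes, vdf, param)
        entry <- list()
        if (!is.null(res$regions)) {
            entry$regions <- lapply(res$regions[c("START", "STOP")], function(r)
                if (is.null(r$fail)) list(start = r$s, end = r$e, shifted = r$shifted)
                else list(fail = r$fail))
        }
        if (!is.null(res$fail)) {
            entry$fail <- res$fail; entry$stage <- res$stage
        } else {
            entry$design <- res$design
        }
        truth$genes[[gid]] <- entry
    }

    # --- plant a diagnostic primer pair (+ nested outer pair) for gene01
    t1 <- truth$genes[["gene01"]]
    if (!is.null(t1$design)) {
        d <- t1$design
        pk <- 20L
        findPrimerPair <- function(innerGapLo, innerGapHi) {
            for (try in seq_len(25L)) {
                dF <- sample(innerGapLo:innerGapHi, 1L)
                dR <- sample(innerGapLo:innerGapHi, 1L)
                fS <- d$cut1 - dF - pk + 1L
                rS <- d$cut2 + dR
                if (fS < 1L || rS + pk - 1L > genomeLength) next
                fwd <- substr(chromStr, fS, fS + pk - 1L)
                rev_ <- revcompChr(substr(chromStr, rS, rS + pk - 1L))
                if (grepl("N", fwd) || grepl("N", rev_)) next
                if (countHits(genome, fwd) != 1L || countHits(genome, rev_) != 1L) next
                return(list(forward = fwd, reverse = rev_, fS = fS,
                            rE = rS + pk - 1L))
            }
            NULL
        }
        inner <- findPrimerPair(60L, 200L)
        outer <- if (!is.null(inner)) findPrimerPair(230L, 380L) else NULL
        if (!is.null(inner)) {
            wt <- inner$rE - inner$fS + 1L
            truth$primers <- list(inner = list(
                name = "gene01_inner", forward = inner$forward,
                reverse = inner$reverse, tier = "INNER",
                wt_size = wt, del_size = wt - d$size))
            if (!is.null(outer)) {
                wtO <- outer$rE - outer$fS + 1L
                truth$primers$outer <- list(
                    name = "gene01_outer", forward = outer$forward,
                    reverse = outer$reverse, tier = "OUTER",
                    wt_size = wtO, del_size = wtO - d$size)
            }
        }
    }

    new("FixtureBundle", seed = as.integer(seed), difficulty = difficulty,
        genome = genome, genes = genes, variants = variantsToGRanges(vdf),
        truth = truth)
}

#' Apply edits to an assembly and record the implied variants
#'
#' Applies substitutions, insertions and deletions to a reference assembly
#' and returns the mutated assembly together with the corresponding VCF-style
#' variant records in reference coordinates. Round trip: applying the
#' returned records to the reference reproduces the mutated assembly.
#'
#' @param genome \code{DNAStringSet}.
#' @param edits data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{type} (SNP/INS/DEL) and \code{value}: for SNP the replacement
#'   base, for INS the inserted sequence (placed after \code{pos}), for DEL
#'   the number of bases deleted starting at \code{pos + 1} (anchor-base
#'   convention, as in VCF).
#' @return list with \code{genome} (mutated \code{DNAStringSet}) and
#'   \code{variants} (\code{GRanges} with ref/alt/type, label "edited").
#' @export
mutateAssembly <- function(genome, edits) {
    stopifnot(all(c("chrom", "pos", "type", "value") %in% names(edits)))
    affEnd <- vapply(seq_len(nrow(edits)), function(i)
        if (edits$type[i] == "DEL")
            edits$pos[i] + as.integer(edits$value[i])
        else edits$pos[i], numeric(1))
    for (chrom in unique(edits$chrom)) {
        i <- which(edits$chrom == chrom)
        o <- i[order(edits$pos[i])]
        if (length(o) > 1L && any(edits$pos[o][-1L] <= affEnd[o][-length(o)]))
            stopInputError("InputError", "overlapping edits")
    }
    rows <- list()
    out <- as.list(as.character(genome))
    for (chrom in unique(edits$chrom)) {
        cs <- out[[chrom]]
        sel <- which(edits$chrom == chrom)
        sel <- sel[order(-edits$pos[sel])]       # right to left
        for (i in sel) {
            p <- edits$pos[i]; v <- as.character(edits$value[i])
            refBase <- substr(cs, p, p)
            if (edits$type[i] == "SNP") {
                rows[[length(rows) + 1L]] <- data.frame(chrom = chrom,
                    start = p, end = p, ref = refBase, alt = v, type = "SNP",
                    label = "edited", stringsAsFactors = FALSE)
                substr(cs, p, p) <- v
            } else if (edits$type[i] == "INS") {
                rows[[length(rows) + 1L]] <- data.frame(chrom = chrom,
                    start = p, end = p, ref = refBase,
                    alt = paste0(refBase, v), type = "INS",
                    label = "edited", stringsAsFactors = FALSE)
                cs <- paste0(substr(cs, 1L, p), v,
                             substr(cs, p + 1L, nchar(cs)))
            } else if (edits$type[i] == "DEL") {
                dlen <- as.integer(v)
                rows[[length(rows) + 1L]] <- data.frame(chrom = chrom,
                    start = p, end = p + dlen,
                    ref = substr(cs, p, p + dlen), alt = refBase,
                    type = "DEL", label = "edited", stringsAsFactors = FALSE)
                cs <- paste0(substr(cs, 1L, p),
                             substr(cs, p + dlen + 1L, nchar(cs)))
            } else stopInputError("InputError",
                sprintf("unknown edit type '%s'", edits$type[i]))
        }
        out[[chrom]] <- cs
    }
    list(genome = DNAStringSet(unlist(out)),
         variants = variantsToGRanges(do.call(rbind, rows)))
}

# --- writers ---------------------------------------------------------------

writeSitesVcf <- function(vdf, genome, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 sprintf("##contig=<ID=%s,length=%d>", names(genome),
                         width(genome)),
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    if (nrow(vdf))
        writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                           vdf$chrom, vdf$start, vdf$ref, vdf$alt), con)
    invisible(path)
}

#' Write a fixture bundle to disk
#'
#' Emits genome.fa, genes.gff3, one sites-only VCF per background label,
#' truth.json, guides.tsv (the planted design's target sequences, for
#' audit runs) and primers.tsv when primer pairs were planted. All files
#' are plain text and re-parse losslessly through the package readers.
#'
#' @param bundle a \linkS4class{FixtureBundle}.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(genome = file.path(dir, "genome.fa"),
               gff = file.path(dir, "genes.gff3"),
               truth = file.path(dir, "truth.json"))
    writeGenome(bundle@genome, files[["genome"]])

    rows <- list()
    for (g in bundle@genes) {
        cds <- unlist(transcripts(g))
        gspan <- GRanges(g@chrom, IRanges(min(start(cds)), max(end(cds))),
                         g@geneStrand)
        mcols(gspan) <- DataFrame(type = "gene", ID = geneID(g),
                                  Parent = NA_character_,
                                  phase = NA_integer_)
        rows[[length(rows) + 1L]] <- gspan
        txl <- transcripts(g)
        for (tn in names(txl)) {
            tx <- txl[[tn]]
            tspan <- GRanges(g@chrom, IRanges(min(start(tx)), max(end(tx))),
                             g@geneStrand)
            mcols(tspan) <- DataFrame(type = "mRNA", ID = tn,
                                      Parent = geneID(g),
                                      phase = NA_integer_)
            rows[[length(rows) + 1L]] <- tspan
            cdsr <- tx
            # phase: bases to skip before the first complete codon, in
            # transcription order
            w <- width(tx)
            if (g@geneStrand == "-") w <- rev(w)
            ph <- c(0L, (3L - cumsum(w)[-length(w)] %% 3L) %% 3L)
            if (g@geneStrand == "-") ph <- rev(ph)
            mcols(cdsr) <- DataFrame(type = "CDS",
                                     ID = paste0(tn, ".cds"),
                                     Parent = tn, phase = ph)
            rows[[length(rows) + 1L]] <- cdsr
        }
    }
    gff <- do.call(c, rows)
    mcols(gff)$type <- factor(mcols(gff)$type, levels = c("gene", "mRNA", "CDS"))
    rtracklayer::export(gff, files[["gff"]], format = "gff3")

    vdf <- data.frame(chrom = as.character(seqnames(bundle@variants)),
                      start = start(bundle@variants),
                      ref = mcols(bundle@variants)$ref,
                      alt = mcols(bundle@variants)$alt,
                      label = mcols(bundle@variants)$label,
                      stringsAsFactors = FALSE)
    for (lab in unique(c("S2Rplus", "attP40", vdf$label))) {
        p <- file.path(dir, paste0(lab, ".vcf"))
        writeSitesVcf(vdf[vdf$label == lab, , drop = FALSE], bundle@genome, p)
        files[[paste0("vcf_", lab)]] <- p
    }

    jsonlite::write_json(bundle@truth, files[["truth"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

    gtab <- do.call(rbind, lapply(names(bundle@truth$genes), function(gid) {
        e <- bundle@truth$genes[[gid]]
        if (is.null(e$design)) return(NULL)
        data.frame(gene = gid,
                   target = c(e$design$proto_start, e$design$proto_stop),
                   role = c("START", "STOP"), stringsAsFactors = FALSE)
    }))
    if (!is.null(gtab)) {
        files[["guides"]] <- file.path(dir, "guides.tsv")
        write.table(gtab, files[["guides"]], sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    if (!is.null(bundle@truth$primers)) {
        pt <- do.call(rbind, lapply(bundle@truth$primers, function(p)
            data.frame(name = p$name, forward = p$forward,
                       reverse = p$reverse, tier = p$tier,
                       stringsAsFactors = FALSE)))
        files[["primers"]] <- file.path(dir, "primers.tsv")
        write.table(pt, files[["primers"]], sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    invisible(files)
}
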