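proto <- "TACGTACGTACGTACGTACG"

test_that("variant overlap uses the protospacer-plus-PAM footprint", {
    g <- makeGuideRow("c1", 101, "+", proto)   # footprint 101..123
    expect_length(variantOverlaps(g, GRanges())[[1]], 0L)

    # SNP at seed position 3 (protospacer position 11, reference 111)
    hit <- variantOverlaps(g, oneVariant("c1", 111, 111))[[1]]
    expect_length(hit, 1L)

    # 4-bp deletion spanning the protospacer/PAM boundary
    del <- oneVariant("c1", 119, 122, ref = "ACGT", alt = "A", type = "DEL")
    expect_length(variantOverlaps(g, del)[[1]], 1L)

    # just outside on either side: no hit
    expect_length(variantOverlaps(g, oneVariant("c1", 100, 100))[[1]], 0L)
    expect_length(variantOverlaps(g, oneVariant("c1", 124, 124))[[1]], 0L)

    # insertions count via their single anchor base
    ins <- oneVariant("c1", 105, 105, ref = "A", alt = "ACCC", type = "INS")
    expect_length(variantOverlaps(g, ins)[[1]], 1L)
})

test_that("variant screen is label-monotone", {
    genome <- chr1(plantedGuideGenome(300, at = 101, proto = proto))
    g <- makeGuideRow("c1", 101, "+", proto)
    v1 <- oneVariant("c1", 111, 111, label = "S2Rplus")
    v2 <- oneVariant("c1", 200, 200, label = "attP40")
    passWith <- function(v) screenGuides(g, genome, v)$verdict == "PASS"
    expect_true(passWith(GRanges()))
    expect_true(passWith(v2))
    expect_false(passWith(c(v2, v1)))   # adding a set can only shrink PASS
})

test_that("off-target search finds planted duplicates and respects the seed", {
    set.seed(31)
    base <- rndDNA(5000)
    base <- gsub("G", "A", base); base <- gsub("C", "T", base)
    substr(base, 101, 123) <- paste0(proto, "TGG")
    g <- makeGuideRow("c1", 101, "+", proto)

    # unique site: no off-targets by either route
    genome <- chr1(base)
    expect_length(findOfftargets(g, genome), 0L)
    expect_equal(nrow(bruteForceOfftargets(proto, genome,
        onTarget = list(chrom = "c1", strand = "+", start = 101))), 0L)

    # exact duplicate elsewhere
    s <- base; substr(s, 2001, 2023) <- paste0(proto, "AGG")
    ot <- findOfftargets(g, chr1(s))
    expect_length(ot, 1L)
    expect_equal(start(ot), 2001)
    expect_equal(mcols(ot)$mm_total, 0L)
    expect_identical(mcols(ot)$pam_type, "NGG")

    # two mismatches outside the seed, NAG PAM: still a hit
    mut <- proto
    substr(mut, 2, 2) <- "G"; substr(mut, 5, 5) <- "C"
    s <- base; substr(s, 2001, 2023) <- paste0(mut, "TAG")
    ot <- findOfftargets(g, chr1(s))
    expect_length(ot, 1L)
    expect_equal(mcols(ot)$mm_total, 2L)
    expect_equal(mcols(ot)$mm_seed, 0L)
    expect_identical(mcols(ot)$pam_type, "NAG")

    # one seed mismatch: invisible under the default seed-exact criterion,
    # visible when the seed tolerance is relaxed
    mut <- proto; substr(mut, 15, 15) <- "A"
    s <- base; substr(s, 2001, 2023) <- paste0(mut, "TGG")
    expect_length(findOfftargets(g, chr1(s)), 0L)
    relaxed <- GuideDesignParam(maxMMSeed = 1L)
    expect_length(findOfftargets(g, chr1(s), relaxed), 1L)
})

test_that("duplicates on the minus strand are found", {
    set.seed(32)
    base <- rndDNA(4000)
    base <- gsub("G", "A", base); base <- gsub("C", "T", base)
    substr(base, 101, 123) <- paste0(proto, "TGG")
    s <- base
    substr(s, 3001, 3023) <- paste0("CCA", rcOracle(proto))
    g <- makeGuideRow("c1", 101, "+", proto)
    ot <- findOfftargets(g, chr1(s))
    expect_length(ot, 1L)
    expect_identical(as.character(strand(ot)), "-")
    expect_equal(start(ot), 3004)
    expect_equal(mcols(ot)$mm_total, 0L)
})

test_that("relaxing off-target parameters never loses hits", {
    set.seed(33)
    for (rep in 1:5) {
        genome <- chr1(rndDNA(20000))
        cand <- scanProtospacers(GRanges("c1", IRanges(5001, 5100)), genome)
        if (length(cand) == 0L) next
        g <- cand[1]
        base <- length(findOfftargets(g, genome, GuideDesignParam()))
        for (p in list(GuideDesignParam(maxMMSeed = 1L),
                       GuideDesignParam(maxMMTotal = 4L),
                       GuideDesignParam(maxMMSeed = 2L, maxMMTotal = 4L))) {
            expect_gte(length(findOfftargets(g, genome, p)), base)
        }
        strict <- length(findOfftargets(g, genome,
            GuideDesignParam(offtargetPAMs = "NGG")))
        expect_lte(strict, base)
    }
})

test_that("efficiency scoring is an affine rescale of the weight sum", {
    zero <- matrix(0, 4, 20, dimnames = list(c("A", "C", "G", "T"), NULL))
    expect_equal(efficiencyScore(c(proto, strrep("A", 20)), zero), c(5, 5))

    g20 <- zero; g20["G", 20] <- 1
    hi <- efficiencyScore(paste0(strrep("A", 19), "G"), g20)
    lo <- efficiencyScore(strrep("A", 20), g20)
    expect_gt(hi, lo)
    expect_equal(hi, 10); expect_equal(lo, 0)

    # ranking of random guides equals an independent recomputation
    set.seed(34)
    w <- defaultEfficiencyWeights()
    guides <- vapply(1:16, function(i) rndDNA(20), character(1))
    got <- efficiencyScore(guides, w)
    raw <- vapply(guides, function(p) {
        b <- strsplit(p, "")[[1]]
        tot <- 0
        for (j in seq_along(b)) tot <- tot + w[b[j], j]
        tot
    }, numeric(1))
    lo_ <- sum(apply(w, 2, min)); hi_ <- sum(apply(w, 2, max))
    expect_equal(got, unname(10 * (raw - lo_) / (hi_ - lo_)))
    expect_true(all(got >= 0 & got <= 10))
})

test_that("screen verdicts compose the three criteria", {
    genome <- chr1(plantedGuideGenome(400, at = 101, proto = proto))
    g <- makeGuideRow("c1", 101, "+", proto)

    expect_identical(screenGuides(g, genome)$verdict, "PASS")

    withSNP <- screenGuides(g, genome, oneVariant("c1", 115, 115))
    expect_identical(withSNP$verdict, "FAIL_VARIANT")
    expect_equal(withSNP$nVariantHits, 1L)

    s <- as.character(genome[[1]])
    substr(s, 301, 323) <- paste0(proto, "AGG")
    withDup <- screenGuides(g, chr1(s))
    expect_identical(withDup$verdict, "FAIL_OFFTARGET")
    expect_equal(withDup$nOfftargets, 1L)

    floor10 <- GuideDesignParam(efficiencyFloor = 10)
    expect_identical(screenGuides(g, genome, param = floor10)$verdict,
                     "FAIL_EFFICIENCY")
})
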