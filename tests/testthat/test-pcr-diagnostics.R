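# deterministic template with unique planted primer sites around a deletion
mkTemplate <- function(seed = 61, len = 3000L, cut1 = 1200L, cut2 = 1983L) {
    set.seed(seed)
    chromStr <- rndDNA(len)
    genome <- chr1(chromStr)
    d <- mkDesignPCR("c1", cut1, cut2, genome)
    list(chromStr = chromStr, genome = genome, d = d)
}

mkDesignPCR <- function(chrom, cut1, cut2, genome) {
    p1 <- "TACGTACGTACGTACGTACG"; p2 <- "ACGTACGTACGTACGTACGT"
    g1 <- makeGuideRow(chrom, cut1 - 16L, "+", p1, role = "START")
    g2 <- makeGuideRow(chrom, cut2 - 16L, "+", p2, role = "STOP")
    new("DeletionDesign", geneID = "gX", chrom = chrom,
        guideStart = g1, guideStop = g2,
        cut1 = as.integer(cut1), cut2 = as.integer(cut2),
        deletionSize = as.integer(cut2 - cut1),
        oligos = cloningOligos(c(p1, p2)),
        alternates = data.frame(), param = GuideDesignParam())
}

primerAt <- function(chromStr, s, rc = FALSE) {
    p <- substr(chromStr, s, s + 19L)
    if (rc) rcOracle(p) else p
}

test_that("locatePrimer reports exact hits on both strands", {
    set.seed(62)
    chromStr <- rndDNA(800)
    g <- chr1(chromStr)
    p <- substr(chromStr, 10, 29)
    hits <- locatePrimer(g, p)
    plus <- hits[as.character(strand(hits)) == "+"]
    expect_true(any(start(plus) == 10 & end(plus) == 29))

    # plant the reverse complement elsewhere: one hit per strand
    s2 <- chromStr; substr(s2, 501, 520) <- rcOracle(p)
    hits <- locatePrimer(chr1(s2), p)
    expect_setequal(as.character(strand(hits)), c("+", "-"))

    expect_error(locatePrimer(g, "ACGTNACGTACGTACG"), "outside ACGT")
})

test_that("amplicon sizes obey the inclusive 5'-to-5' convention", {
    tm <- mkTemplate()
    fwd <- primerAt(tm$chromStr, 1000)              # fS = 1000
    rev_ <- primerAt(tm$chromStr, 2180, rc = TRUE)  # site 2180..2199
    pred <- predictAmplicon("p", fwd, rev_, tm$genome, tm$d)
    expect_identical(pred@status, "OK")
    expect_equal(pred@wtSize, 2199 - 1000 + 1)
    expect_equal(pred@wtSize - pred@delSize, deletionSize(tm$d))
    expect_true(pred@wtDetectable && pred@delDetectable)
    expect_match(pred@biasNote, "smaller")

    # without a design only the wild-type product is predicted
    noDel <- predictAmplicon("p", fwd, rev_, tm$genome)
    expect_equal(noDel@wtSize, pred@wtSize)
    expect_true(is.na(noDel@delSize))

    # swapping forward/reverse labels does not change the prediction
    swapped <- predictAmplicon("p", rev_, fwd, tm$genome, tm$d)
    expect_equal(swapped@wtSize, pred@wtSize)
    expect_equal(swapped@delSize, pred@delSize)
})

test_that("the deletion amplicon equals the string-surgery product", {
    tm <- mkTemplate(63)
    fwd <- primerAt(tm$chromStr, 1050)
    rev_ <- primerAt(tm$chromStr, 2100, rc = TRUE)
    pred <- predictAmplicon("p", fwd, rev_, tm$genome, tm$d)
    alleleStr <- surgeryOracle(tm$chromStr, tm$d@cut1, tm$d@cut2)
    fS <- regexpr(fwd, alleleStr, fixed = TRUE)
    rS <- regexpr(rcOracle(rev_), alleleStr, fixed = TRUE)
    expect_equal(pred@delSize, as.integer(rS) + 19 - as.integer(fS) + 1)
    amplicon <- substr(alleleStr, fS, rS + 19)
    expect_equal(nchar(amplicon), pred@delSize)
    expect_identical(substr(amplicon, 1, 20), fwd)
})

test_that("primer failures are reported as statuses", {
    tm <- mkTemplate(64)
    fwdIn <- primerAt(tm$chromStr, tm$d@cut1 + 100)     # inside the deletion
    rev_ <- primerAt(tm$chromStr, 2200, rc = TRUE)
    pred <- predictAmplicon("p", fwdIn, rev_, tm$genome, tm$d)
    expect_identical(pred@status, "PrimerLost")
    expect_true(is.na(pred@delSize))
    expect_false(pred@delDetectable)

    # ambiguous: plant a second copy of the forward primer
    s2 <- tm$chromStr
    fwd <- primerAt(tm$chromStr, 1000)
    substr(s2, 2700, 2719) <- fwd
    pred <- predictAmplicon("p", fwd, rev_, chr1(s2), tm$d)
    expect_identical(pred@status, "AmbiguousPrimer")

    # divergent: primers on different chromosomes
    g2 <- Biostrings::DNAStringSet(c(c1 = tm$chromStr,
                                     c2 = paste0(rcOracle(rev_), rndDNA(80))))
    pred <- predictAmplicon("p", fwd, rev_, g2, tm$d)
    expect_identical(pred@status, "AmbiguousPrimer")  # rev now maps twice

    g3 <- Biostrings::DNAStringSet(c(
        c1 = substr(tm$chromStr, 1, 1100),
        c2 = paste0(rndDNA(50), rcOracle(rev_), rndDNA(50))))
    pred <- predictAmplicon("p", fwd, rev_, g3, NULL)
    expect_identical(pred@status, "Divergent")

    pred <- predictAmplicon("p", strrep("A", 20), rev_, tm$genome, tm$d)
    expect_identical(pred@status, "NoProduct")
})

test_that("oversized products are flagged undetectable", {
    set.seed(65)
    chromStr <- rndDNA(9000)
    genome <- chr1(chromStr)
    fwd <- substr(chromStr, 100, 119)
    rev_ <- rcOracle(substr(chromStr, 7000, 7019))
    pred <- predictAmplicon("big", fwd, rev_, genome,
                            param = GuideDesignParam())
    expect_identical(pred@status, "OK")
    expect_equal(pred@wtSize, 7019 - 100 + 1)
    expect_false(pred@wtDetectable)
    expect_match(pred@detail, "warn tier")
})

test_that("nested plans check containment on both alleles", {
    tm <- mkTemplate(66)
    outer <- list(name = "o", forward = primerAt(tm$chromStr, 900),
                  reverse = primerAt(tm$chromStr, 2300, rc = TRUE))
    inner <- list(name = "i", forward = primerAt(tm$chromStr, 1000),
                  reverse = primerAt(tm$chromStr, 2150, rc = TRUE))
    np <- nestedPlan(outer, inner, tm$genome, tm$d)
    expect_identical(np$status, "OK")
    expect_true(np$containedReference)
    expect_true(np$containedDeletion)
    expect_lte(np$inner@wtSize, np$outer@wtSize)
    expect_lte(np$inner@delSize, np$outer@delSize)
    expect_equal(np$outer@wtSize - np$outer@delSize, deletionSize(tm$d))

    # inner forward upstream of outer forward: not nested
    badInner <- list(name = "i", forward = primerAt(tm$chromStr, 850),
                     reverse = inner$reverse)
    np <- nestedPlan(outer, badInner, tm$genome, tm$d)
    expect_identical(np$status, "InnerOutsideOuter")
})

test_that("nested sizes stay ordered over random concentric layouts", {
    set.seed(67)
    for (rep in 1:10) {
        L <- 4000L
        chromStr <- rndDNA(L)
        genome <- chr1(chromStr)
        cut1 <- 1500L; cut2 <- cut1 + sample(300:900, 1)
        d <- mkDesignPCR("c1", cut1, cut2, genome)
        oF <- sample(200:700, 1); oR <- sample((cut2 + 300):(cut2 + 700), 1)
        iF <- oF + sample(30:180, 1); iR <- oR - sample(30:180, 1)
        if (iR - 19 <= cut2) next
        outer <- list(name = "o", forward = primerAt(chromStr, oF),
                      reverse = primerAt(chromStr, oR - 19, rc = TRUE))
        inner <- list(name = "i", forward = primerAt(chromStr, iF),
                      reverse = primerAt(chromStr, iR - 19, rc = TRUE))
        np <- nestedPlan(outer, inner, genome, d)
        if (np$status != "OK") next   # rare multi-mapping primers
        expect_lte(np$inner@wtSize, np$outer@wtSize)
        expect_lte(np$inner@delSize, np$outer@delSize)
        expect_equal(np$inner@wtSize - np$inner@delSize, cut2 - cut1)
    }
})
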