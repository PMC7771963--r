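# a DeletionDesign with prescribed cuts, for arithmetic-only tests
mkDesign <- function(chrom, cut1, cut2, genome,
                     p1 = "TACGTACGTACGTACGTACG",
                     p2 = "ACGTACGTACGTACGTACGT") {
    g1 <- makeGuideRow(chrom, cut1 - 16L, "+", p1, role = "START")
    g2 <- makeGuideRow(chrom, cut2 - 16L, "+", p2, role = "STOP")
    new("DeletionDesign", geneID = "gX", chrom = chrom,
        guideStart = g1, guideStop = g2,
        cut1 = as.integer(cut1), cut2 = as.integer(cut2),
        deletionSize = as.integer(cut2 - cut1),
        oligos = cloningOligos(c(p1, p2)),
        alternates = data.frame(), param = GuideDesignParam())
}

test_that("candidate ranking follows efficiency, adjacency, coordinate", {
    p1 <- strrep("A", 20)                       # low score
    p2 <- paste0(strrep("A", 19), "G")          # high score (G at 20)
    guides <- c(makeGuideRow("c1", 101, "+", p1),
                makeGuideRow("c1", 201, "+", p2))
    genome <- chr1(strrep("T", 400))
    sc <- S4Vectors::DataFrame(protospacer = c(p1, p2),
                               efficiency = c(5.0, 7.1),
                               nVariantHits = c(0L, 0L),
                               nOfftargets = c(0L, 0L),
                               verdict = c("PASS", "PASS"))
    expect_equal(rankCandidates(guides, sc), c(2L, 1L))

    # equal efficiency: lower cut coordinate wins
    sc$efficiency <- c(6, 6)
    expect_equal(rankCandidates(guides, sc), c(1L, 2L))

    # random report sets: ordering equals a naive sort oracle
    set.seed(41)
    for (rep in 1:20) {
        n <- 8L
        gs <- do.call(c, lapply(seq_len(n), function(i)
            makeGuideRow("c1", 100L + 30L * i, "+", rndDNA(20))))
        eff <- round(runif(n, 0, 10), 1)
        verd <- sample(c("PASS", "FAIL_VARIANT"), n, replace = TRUE)
        sc <- S4Vectors::DataFrame(protospacer = mcols(gs)$protospacer,
                                   efficiency = eff,
                                   nVariantHits = 0L, nOfftargets = 0L,
                                   verdict = verd)
        got <- rankCandidates(gs, sc)
        idx <- which(verd == "PASS")
        want <- idx[order(-eff[idx], mcols(gs)$cut_after[idx])]
        expect_identical(got, want)
    }
})

test_that("the designed pair matches the planted fixture optimum", {
    b <- makeBundle(51, "CLEAN", genomeLength = 12000)
    t <- b@truth$genes$gene01
    expect_false(is.null(t$design))
    d <- designDeletion(b@genes$gene01, b@genome, b@genes, b@variants)
    expect_true(matchesTruth(d, t))
    expect_identical(mcols(d@guideStart)$region_role, "START")
    expect_identical(mcols(d@guideStop)$region_role, "STOP")
    expect_gte(deletionSize(d), 200L)
    # alternates are distinct from, and no better than, the chosen pair
    alt <- alternatePairs(d)
    if (nrow(alt)) {
        eff <- efficiencyScore(c(d@guideStart, d@guideStop))
        expect_true(all(alt$efficiency_sum <= sum(eff) + 1e-9))
    }
})

test_that("the chosen pair is the argmax over the PASS x PASS grid", {
    for (seed in c(52, 53)) {
        b <- makeBundle(seed, "CLEAN", genomeLength = 12000)
        if (is.null(b@truth$genes$gene01$design)) next
        d <- designDeletion(b@genes$gene01, b@genome, b@genes, b@variants)
        # independent exhaustive grid: rescreen both regions and enumerate
        r <- selectTargetRegions(b@genes$gene01, b@genome, b@genes)
        gs <- scanProtospacers(r[1], b@genome)
        gt <- scanProtospacers(r[2], b@genome)
        ss <- screenGuides(gs, b@genome, b@variants)
        st <- screenGuides(gt, b@genome, b@variants)
        best <- -Inf; bestPair <- NULL
        for (i in which(ss$verdict == "PASS")) for (j in which(st$verdict == "PASS")) {
            if (abs(mcols(gt)$cut_after[j] - mcols(gs)$cut_after[i]) < 200) next
            e <- ss$efficiency[i] + st$efficiency[j]
            if (e > best + 1e-12) { best <- e; bestPair <- c(i, j) }
        }
        expect_equal(sum(efficiencyScore(c(d@guideStart, d@guideStop))), best,
                     tolerance = 1e-9)
    }
})

test_that("short single-exon genes cannot satisfy the minimum separation", {
    set.seed(42)
    genome <- chr1(rndDNA(2000))
    g <- GeneModel("tiny", "c1", "+",
                   list(GRanges("c1", IRanges(501, 650))))  # 150 bp CDS
    err <- tryCatch(designDeletion(g, genome, list(g), GRanges()),
                    error = identity)
    expect_s3_class(err, "NoViablePair")
})

test_that("deletion arithmetic and the blunt-join allele are consistent", {
    set.seed(43)
    chromStr <- rndDNA(1500)
    genome <- chr1(chromStr)
    d <- mkDesign("c1", 117, 900, genome)
    expect_equal(deletionSize(d), 783)
    expect_equal(start(deletionInterval(d)), 118)
    expect_equal(end(deletionInterval(d)), 900)

    allele <- deletionAllele(d, genome)
    expect_equal(length(allele[["c1"]]), 1500 - 783)
    # junction equals independent string surgery
    expect_identical(as.character(allele[["c1"]]),
                     surgeryOracle(chromStr, 117, 900))
    expect_identical(junctionSequence(d, genome, flank = 25),
                     paste0(substr(chromStr, 93, 117),
                            substr(chromStr, 901, 925)))
})

test_that("the re-ligated allele splits both protospacer+PAM sites", {
    for (seed in c(54, 55)) {
        b <- makeBundle(seed, "CLEAN", genomeLength = 12000)
        if (is.null(b@truth$genes$gene01$design)) next
        d <- designDeletion(b@genes$gene01, b@genome, b@genes, b@variants)
        allele <- as.character(deletionAllele(d, b@genome)[[d@chrom]])
        for (g in list(d@guideStart, d@guideStop)) {
            site <- paste0(mcols(g)$protospacer, mcols(g)$pam)
            expect_false(grepl(site, allele, fixed = TRUE))
            expect_false(grepl(rcOracle(site), allele, fixed = TRUE))
        }
    }
})

test_that("designs are byte-identical across repeated runs", {
    b <- makeBundle(56, "CLEAN", genomeLength = 12000)
    out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
    designGenes(b@genome, b@genes, b@variants, genes = "gene01", outDir = out1)
    designGenes(b@genome, b@genes, b@variants, genes = "gene01", outDir = out2)
    for (f in list.files(out1)) {
        expect_identical(readLines(file.path(out1, f)),
                         readLines(file.path(out2, f)), label = f)
    }
})
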