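test_that("bundles regenerate byte-identically from the same seed", {
    b1 <- makeBundle(71, "SNP_DENSE", genomeLength = 11000)
    b2 <- makeBundle(71, "SNP_DENSE", genomeLength = 11000)
    expect_identical(as.character(b1@genome), as.character(b2@genome))
    expect_identical(b1@truth, b2@truth)
    expect_identical(as.data.frame(b1@variants), as.data.frame(b2@variants))

    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    f1 <- writeBundle(b1, d1); f2 <- writeBundle(b2, d2)
    expect_identical(names(f1), names(f2))
    for (k in names(f1))
        expect_identical(unname(tools::md5sum(f1[[k]])),
                         unname(tools::md5sum(f2[[k]])), label = k)
})

test_that("bundle generation does not disturb the caller's RNG stream", {
    set.seed(99); a <- runif(1)
    set.seed(99); invisible(makeBundle(72, "CLEAN", genomeLength = 10000))
    b <- runif(1)
    expect_identical(a, b)
})

test_that("emitted files parse back losslessly through the readers", {
    for (seed in c(73, 74)) {
        b <- makeBundle(seed, sample(DIFFS, 1), genomeLength = 11000)
        dir <- withr::local_tempdir()
        files <- writeBundle(b, dir)
        g <- readGenome(files[["genome"]])
        expect_identical(as.character(g), as.character(b@genome))
        gm <- readGeneModels(files[["gff"]])
        for (gid in names(b@genes)) {
            expect_true(gid %in% names(gm))
            want <- lapply(as.list(transcripts(b@genes[[gid]])),
                           function(x) cbind(start(x), end(x)))
            got <- lapply(as.list(transcripts(gm[[gid]])),
                          function(x) cbind(start(x), end(x)))
            expect_identical(unname(got), unname(want), label = gid)
            expect_identical(gm[[gid]]@geneStrand, b@genes[[gid]]@geneStrand)
        }
        reread <- do.call(c, lapply(c("S2Rplus", "attP40"), function(lab)
            readVariants(files[[paste0("vcf_", lab)]], lab, g)))
        inMem <- b@variants
        expect_equal(length(reread), length(inMem))
        o1 <- order(start(reread), mcols(reread)$label)
        o2 <- order(start(inMem), mcols(inMem)$label)
        expect_identical(start(reread)[o1], start(inMem)[o2])
        expect_identical(mcols(reread)$ref[o1], mcols(inMem)$ref[o2])
        expect_identical(mcols(reread)$alt[o1], mcols(inMem)$alt[o2])
    }
})

test_that("stored truth is reproducible from the emitted files alone", {
    b <- makeBundle(75, "CLEAN", genomeLength = 11000)
    dir <- withr::local_tempdir()
    files <- writeBundle(b, dir)
    g <- readGenome(files[["genome"]])
    gm <- readGeneModels(files[["gff"]])
    vdf <- do.call(rbind, lapply(c("S2Rplus", "attP40"), function(lab) {
        v <- readVariants(files[[paste0("vcf_", lab)]], lab, g)
        data.frame(chrom = as.character(seqnames(v)), start = start(v),
                   end = end(v), ref = mcols(v)$ref, alt = mcols(v)$alt,
                   type = mcols(v)$type, label = lab,
                   stringsAsFactors = FALSE)
    }))
    redo <- dgRNAdesign:::oracleDesign(gm$gene01, g, gm, vdf,
                                       GuideDesignParam())
    t <- b@truth$genes$gene01
    expect_identical(redo$design$proto_start, t$design$proto_start)
    expect_identical(redo$design$proto_stop, t$design$proto_stop)
    expect_equal(redo$design$cut1, t$design$cut1)
    expect_equal(redo$design$cut2, t$design$cut2)
})

test_that("each difficulty plants its hazard", {
    b <- makeBundle(76, "NESTED_ORF", genomeLength = 12000)
    expect_true("nested01" %in% names(b@genes))
    expect_true(b@truth$genes$gene01$regions$START$shifted)

    b <- makeBundle(77, "MULTI_ISOFORM", genomeLength = 12000)
    expect_gte(length(transcripts(b@genes$gene01)), 3L)
    starts <- vapply(as.list(transcripts(b@genes$gene01)),
                     function(x) min(start(x)), numeric(1))
    expect_gt(length(unique(starts)), 1L)

    b <- makeBundle(78, "SNP_DENSE", genomeLength = 12000)
    clean <- makeBundle(78, "CLEAN", genomeLength = 12000)
    expect_gt(length(b@variants), length(clean@variants))
    expect_setequal(unique(mcols(b@variants)$label), c("S2Rplus", "attP40"))

    b <- makeBundle(79, "SINGLE_EXON", genomeLength = 12000)
    expect_length(transcripts(b@genes$gene01)[[1]], 1L)
})

test_that("infeasible parameters are rejected", {
    expect_error(makeBundle(1, "CLEAN", genomeLength = 5000), "10000")
    expect_error(makeBundle(1, "CLEAN", genomeLength = 12000,
                            snpDensity = 0.5), "snpDensity")
    expect_error(makeBundle(1, "CLEAN", genomeLength = 12000, nGenes = 9),
                 "nGenes")
})

test_that("mutateAssembly applies edits and records matching variants", {
    g <- chr1("ACGTACGTACGTACGTACGTACGT")
    res <- mutateAssembly(g, data.frame(chrom = "c1", pos = 5L,
                                        type = "SNP", value = "T"))
    expect_equal(length(res$genome[["c1"]]), 24L)
    expect_identical(substr(as.character(res$genome[["c1"]]), 5, 5), "T")
    expect_identical(mcols(res$variants)$type, "SNP")

    res <- mutateAssembly(g, data.frame(chrom = "c1", pos = 8L,
                                        type = "DEL", value = "4"))
    expect_equal(length(res$genome[["c1"]]), 20L)
    expect_identical(mcols(res$variants)$type, "DEL")
    expect_equal(width(res$variants), 5L)   # anchor + 4 deleted bases

    expect_error(mutateAssembly(g, data.frame(
        chrom = "c1", pos = c(8L, 10L), type = "DEL", value = "4")),
        "overlapping")
})

test_that("recorded variants replay onto the reference (round trip)", {
    set.seed(80)
    ref <- rndDNA(400)
    edits <- data.frame(chrom = "c1",
                        pos = c(50L, 120L, 200L, 300L),
                        type = c("SNP", "INS", "DEL", "SNP"),
                        value = c("T", "GGA", "3", "C"),
                        stringsAsFactors = FALSE)
    # make the SNPs real substitutions
    substr(ref, 50, 50) <- "A"; substr(ref, 300, 300) <- "G"
    res <- mutateAssembly(chr1(ref), edits)
    v <- res$variants
    # independent replay with plain string operations, right to left
    replay <- ref
    o <- order(-start(v))
    for (i in o) {
        p <- start(v)[i]; refA <- mcols(v)$ref[i]; altA <- mcols(v)$alt[i]
        expect_identical(substr(replay, p, p + nchar(refA) - 1L), refA)
        replay <- paste0(substr(replay, 1, p - 1L), altA,
                         substr(replay, p + nchar(refA), nchar(replay)))
    }
    expect_identical(replay, as.character(res$genome[["c1"]]))
})
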