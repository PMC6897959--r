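test_that("a planted protospacer is recovered with the extremal statistic on both strands", {
    for (strand in c("+", "-")) {
        fix <- plantedFixture(6000L, 3000L, strand = strand)
        qc <- spacerQuery(fix$spacer, mode = "consecutive",
                          minConsecutive = 32L)
        sc <- findPotConsecutive(fix$genome, qc)
        hit <- sc[GenomicRanges::start(sc) == 3001L]
        expect_true(length(hit) == 1L)
        expect_equal(S4Vectors::mcols(hit)$consecutiveMatchLen, 32L)
        expect_equal(as.character(GenomicRanges::strand(hit)), strand)
        expect_equal(S4Vectors::mcols(hit)$pamObserved, "AAG")

        qm <- spacerQuery(fix$spacer, mode = "mismatch",
                          maxMismatches = 0L)
        sm <- findPotMismatch(fix$genome, qm)
        hit <- sm[GenomicRanges::start(sm) == 3001L]
        expect_equal(S4Vectors::mcols(hit)$mismatchCount, 0L)
    }
})

test_that("wildcard positions never affect match statistics", {
    fix <- plantedFixture(6000L, 3000L)
    s <- as.character(fix$genome[[1]])
    for (p in c(6L, 12L, 18L, 24L, 30L)) {
        gpos <- 3000L + p             # 1-based genome position of spacer p
        old <- substr(s, gpos, gpos)
        mut <- s
        substr(mut, gpos, gpos) <- setdiff(c("A", "C", "G", "T"), old)[1]
        mref <- Biostrings::DNAStringSet(mut); names(mref) <- "chrS"
        qc <- spacerQuery(fix$spacer, mode = "consecutive",
                          minConsecutive = 32L)
        sc <- findPotConsecutive(mref, qc)
        expect_equal(
            S4Vectors::mcols(sc[GenomicRanges::start(sc) == 3001L]
                             )$consecutiveMatchLen, 32L)
        qm <- spacerQuery(fix$spacer, mode = "mismatch", maxMismatches = 0L)
        sm <- findPotMismatch(mref, qm)
        expect_equal(
            S4Vectors::mcols(sm[GenomicRanges::start(sm) == 3001L]
                             )$mismatchCount, 0L)
    }
})

test_that("a non-wildcard mutation breaks the consecutive run where expected", {
    fix <- plantedFixture(6000L, 3000L)
    s <- as.character(fix$genome[[1]])
    substr(s, 3008L, 3008L) <-
        setdiff(c("A", "C", "G", "T"), substr(s, 3008L, 3008L))[1]
    mref <- Biostrings::DNAStringSet(s); names(mref) <- "chrS"
    qc <- spacerQuery(fix$spacer, mode = "consecutive", minConsecutive = 5L)
    sc <- findPotConsecutive(mref, qc)
    hit <- sc[GenomicRanges::start(sc) == 3001L]
    expect_equal(S4Vectors::mcols(hit)$consecutiveMatchLen, 7L)
    expect_equal(S4Vectors::mcols(hit)$mismatchCount, 1L)
})

test_that("both search modes agree exactly with the brute-force oracle", {
    set.seed(202)
    for (rep in 1:8) {
        gseed <- 300 + rep
        g <- simulateGenome(3000L, gc = runif(1, 0.3, 0.6), seed = gseed)
        sp <- randomSpacer(400 + rep)
        pams <- sample(CAS3_PAM_SET, sample(2:6, 1))
        ref <- refChar(g)

        orc <- oraclePotScan(ref, sp, pams)
        minC <- sample(6:10, 1)
        qc <- spacerQuery(sp, pamSet = pams, mode = "consecutive",
                          minConsecutive = minC)
        sc <- findPotConsecutive(g, qc)
        o <- orc[orc$runLen >= minC, ]
        expect_identical(grKey(sc), siteKey(o$chrom, o$start0, o$strand))
        ## per-site statistics must agree too
        if (length(sc)) {
            om <- o[order(o$chrom, o$start0, o$strand), ]
            expect_equal(S4Vectors::mcols(sc)$consecutiveMatchLen,
                         om$runLen[order(om$chrom, om$start0, om$strand)])
        }

        maxMm <- sample(3:8, 1)
        qm <- spacerQuery(sp, pamSet = pams, mode = "mismatch",
                          maxMismatches = maxMm)
        sm <- findPotMismatch(g, qm)
        o <- orc[orc$mm <= maxMm, ]
        expect_identical(grKey(sm), siteKey(o$chrom, o$start0, o$strand))

        ## Cas9 mode: 20-nt guide, 3' NGG, no wildcards
        guide <- randomSpacer(500 + rep, 20L)
        o9 <- oraclePotScan(ref, guide, "NGG", pamSide = "three_prime",
                            wildcardPeriod = NA)
        s9 <- findPotCas9(g, guide, maxMismatches = 4L)
        o <- o9[o9$mm <= 4L, ]
        expect_identical(grKey(s9), siteKey(o$chrom, o$start0, o$strand))
    }
})

test_that("site sets are monotone in the matching thresholds", {
    g <- simulateGenome(20000L, seed = 31)
    sp <- randomSpacer(32)
    for (mc in c(10L, 8L, 6L)) {
        q <- spacerQuery(sp, mode = "consecutive", minConsecutive = mc)
        s <- findPotConsecutive(g, q)
        if (mc < 10L)
            expect_true(all(prevKeys %in% grKey(s)))
        prevKeys <- grKey(s)
    }
    for (mm in c(4L, 6L, 8L)) {
        q <- spacerQuery(sp, mode = "mismatch", maxMismatches = mm)
        s <- findPotMismatch(g, q)
        if (mm > 4L)
            expect_true(all(prevKeys %in% grKey(s)))
        prevKeys <- grKey(s)
    }
})

test_that("reverse-complementing the reference mirrors every site", {
    g <- simulateGenome(15000L, seed = 77)
    sp <- randomSpacer(78)
    q <- spacerQuery(sp, mode = "mismatch", maxMismatches = 6L)
    s1 <- findPotMismatch(g, q)
    rc <- Biostrings::reverseComplement(g)
    names(rc) <- names(g)
    s2 <- findPotMismatch(rc, q)
    expect_equal(length(s1), length(s2))
    n <- 15000L
    mirrored <- sort(n - (GenomicRanges::end(s1)) + 1L)
    expect_equal(sort(GenomicRanges::start(s2)), mirrored)
    expect_equal(sum(as.character(GenomicRanges::strand(s1)) == "+"),
                 sum(as.character(GenomicRanges::strand(s2)) == "-"))
})

test_that("ambiguity codes in the reference never match, even at wildcard or PAM positions", {
    fix <- plantedFixture(6000L, 3000L)
    s <- as.character(fix$genome[[1]])
    substr(s, 3006L, 3006L) <- "N"   # wildcard position 6
    mref <- Biostrings::DNAStringSet(s); names(mref) <- "chrS"
    qm <- spacerQuery(fix$spacer, mode = "mismatch", maxMismatches = 0L)
    expect_length(findPotMismatch(mref, qm), 0L)
    s <- as.character(fix$genome[[1]])
    substr(s, 2998L, 2998L) <- "N"   # PAM base
    mref <- Biostrings::DNAStringSet(s); names(mref) <- "chrS"
    expect_length(
        findPotMismatch(mref, qm)[GenomicRanges::start(
            findPotMismatch(mref, qm)) == 3001L], 0L)
})

test_that("PAM N-expansion matches any base and invalid spacers are rejected", {
    fix <- plantedFixture(6000L, 3000L, pam = "AAG")
    qn <- spacerQuery(fix$spacer, pamSet = "NNN", mode = "mismatch",
                      maxMismatches = 0L)
    sn <- findPotMismatch(fix$genome, qn)
    expect_true(3001L %in% GenomicRanges::start(sn))
    expect_error(spacerQuery("ACGTX", mode = "mismatch", maxMismatches = 1L))
})

test_that("potReport emits a consistent table, histogram and BED", {
    fix <- plantedFixture(8000L, 3000L)
    q <- spacerQuery(fix$spacer, mode = "mismatch", maxMismatches = 8L)
    sites <- findPotMismatch(fix$genome, q)
    tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
    rep <- potReport(sites, q, fix$genome, tsv = tsv, bed = bed)
    expect_equal(nrow(rep$table), length(sites))
    expect_equal(sum(rep$histogram), length(sites))
    bedLines <- readLines(bed)
    expect_equal(length(bedLines), length(sites))
    f <- strsplit(bedLines[1], "\t")[[1]]
    expect_equal(as.integer(f[2]), GenomicRanges::start(sites)[1] - 1L)
    expect_equal(as.integer(f[3]), GenomicRanges::end(sites)[1])

    empty <- potReport(sites[0], q, tsv = tempfile())
    expect_equal(nrow(empty$table), 0L)
    expect_s3_class(empty$table, "data.frame")
})
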