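test_that("error-free reads recover planted deletion intervals bp-exactly", {
    fix <- plantedFixture(60000L, 50000L)
    als <- simulateCas3Alleles(fix$genome, fix$target,
        editConfig(editRate = 1, upstreamFraction = 1, seed = 7), 10L)
    aln <- simulateAlignments(als, readSimConfig(depth = 120,
        readLength = 100L, insertMean = 400, insertSd = 40, seed = 8))
    calls <- callDeletionsNearTarget(aln, fix$target, flank = 1000L)
    expect_gt(nrow(calls), 0)

    truth <- allelesToCalls(als, fix$target)
    truthKey <- paste(truth$start, truth$end)
    ## every call matches a planted interval exactly (both endpoints)
    expect_true(all(paste(calls$start, calls$end) %in% truthKey))
    ## every planted deletion with at least one junction-crossing read is
    ## called
    rec <- aln$records
    covered <- sort(unique(rec$allele[rec$category == "junction_split"]))
    covRows <- match(sprintf("allele%06d", covered), truth$readId)
    ## only deletions whose breakpoint lies within the 1-kb flank qualify
    covRows <- covRows[abs(truth$startOffset[covRows]) <= 1000L]
    expect_setequal(unique(paste(calls$start, calls$end)),
                    truthKey[covRows])
    ## size bookkeeping and orientation
    expect_true(all(calls$size == calls$end - calls$start))
    expect_true(all(calls$direction == "upstream"))
    expect_true(all(calls$startOffset ==
                        fix$target@pamStart - calls$end))
})

test_that("no split reads near the target yields an empty call set", {
    fix <- plantedFixture(30000L, 25000L)
    unedited <- alleleSet(as.character(fix$genome[[1]]),
                          replicate(2, list(), simplify = FALSE))
    aln <- simulateAlignments(unedited, readSimConfig(depth = 15,
        readLength = 100L, insertMean = 400, insertSd = 40, seed = 2))
    calls <- callDeletionsNearTarget(aln, fix$target)
    expect_equal(nrow(calls), 0L)
})

test_that("deletion summaries compute the documented statistics", {
    tgt <- targetSite("chrS", 10000L, 32L, "+", "AAG")
    one <- data.frame(chrom = "chrS", start = 10000L - 3L - 100L - 2000L,
                      end = 10000L - 3L - 100L, readId = "r1")
    s1 <- summarizeDeletions(cas3edit:::.annotateCalls(one, tgt))
    expect_equal(s1$nCalls, 1L)
    expect_equal(unname(s1$fracLt["lt3000"]), 1)
    expect_equal(s1$fracStartWithin, 1)
    expect_equal(s1$fracUpstream, 1)
    expect_equal(s1$startOffsetMean, 100)

    two <- data.frame(chrom = "chrS",
                      start = c(5897L, 9697L - 12000L),
                      end = c(7897L, 9697L), readId = c("a", "b"))
    s2 <- summarizeDeletions(cas3edit:::.annotateCalls(two, tgt))
    expect_equal(s2$meanSize, 7000)
    expect_equal(unname(s2$fracLt["lt10000"]), 0.5)
    expect_equal(s2$maxSize, 12000)

    ## unique-interval counting: duplicates collapse unless perRead = TRUE
    dup <- rbind(one, transform(one, readId = "r2"))
    expect_equal(summarizeDeletions(
        cas3edit:::.annotateCalls(dup, tgt))$nCalls, 1L)
    expect_equal(summarizeDeletions(
        cas3edit:::.annotateCalls(dup, tgt), perRead = TRUE)$nCalls, 2L)

    expect_equal(summarizeDeletions(
        cas3edit:::.annotateCalls(NULL, tgt))$nCalls, 0L)
})

test_that("generator-level summaries track the configured distributions", {
    big <- plantedFixture(1000000L, 950000L)
    als <- simulateCas3Alleles(big$genome, big$target,
        editConfig(editRate = 1, seed = 13), 4000L)
    calls <- allelesToCalls(als, big$target)
    s <- summarizeDeletions(calls)
    ## upstream fraction ~ Binomial(n, 0.95), 3-sd band
    tol <- 3 * sqrt(0.95 * 0.05 / s$nCalls)
    expect_lt(abs(s$fracUpstream - 0.95), tol)
    ## start offsets ~ Exp(217): mean within 3 se
    expect_lt(abs(s$startOffsetMean - 217), 3 * 217 / sqrt(s$nCalls) + 1)
})

test_that("amplicon efficiency recovers the edit rate and exposes probe bias", {
    fix <- plantedFixture(40000L, 30000L)
    parent <- as.character(fix$genome[[1]])

    flat <- alleleSet(parent, replicate(3, list(), simplify = FALSE))
    d0 <- simulateAmpliconDepth(flat, 25000L, 34000L, seed = 1)
    e0 <- ampliconEfficiency(d0, fix$target)
    expect_equal(e0$value, 0, tolerance = 3)

    ## all alleles deleted at the edited probe -> 100%
    probe <- fix$target@pamStart - 300L
    als1 <- alleleSet(parent,
        list(list(list(type = "deletion", start = probe - 2000L,
                       end = probe + 500L))))
    d1 <- simulateAmpliconDepth(als1, 25000L, 34000L, seed = 2)
    expect_equal(ampliconEfficiency(d1, fix$target)$value, 100)

    ## 30% edited with probe-covering deletions -> ~30%
    als <- simulateCas3Alleles(fix$genome, fix$target,
        editConfig(editRate = 0.3, startOffsetMean = 50,
                   sizeMeanlog = log(5000), sizeSdlog = 0.2,
                   upstreamFraction = 1, seed = 3), 2000L)
    d <- simulateAmpliconDepth(als, 25000L, 34000L, seed = 4)
    eff <- ampliconEfficiency(d, fix$target)
    expect_gte(eff$value, 28)
    expect_lte(eff$value, 32)

    ## bias: deletions that start beyond the probe offset are invisible
    far <- alleleSet(parent,
        list(list(list(type = "deletion", start = probe - 6000L,
                       end = probe - 1000L)), list(), list()),
        weights = c(0.3, 0.4, 0.3))
    dFar <- simulateAmpliconDepth(far, 25000L, 34000L, seed = 5)
    expect_lt(ampliconEfficiency(dFar, fix$target)$value, 5)

    expect_error(ampliconEfficiency(d0[d0$pos > 29900, ], fix$target),
                 "outside")
})

test_that("the PDD calibration reproduces its anchors and scales linearly", {
    cal <- pddCalibration(5.24, 16.1)
    expect_identical(pddToEfficiency(5.24, cal), 16.1)
    expect_identical(pddToEfficiency(0, cal), 0)
    expect_equal(pddToEfficiency(3.5, cal), 3.5 * 16.1 / 5.24)
    expect_identical(pddToEfficiency(1000, cal), 100)  # clamp
    expect_error(pddCalibration(0, 10))
})

test_that("inversion evidence is counted and deletions contribute none", {
    g <- simulateGenome(40000L, seed = 6)
    parent <- as.character(g[[1]])
    siteA <- targetSite("chrS", 15000L, 32L, "+", "AAG")
    siteB <- targetSite("chrS", 25000L, 32L, "+", "AAG")

    inv <- simulateInversionAllele(g, 15032L, 25000L, invFraction = 0.5,
                                   nAlleles = 4L)
    aln <- simulateAlignments(inv, readSimConfig(depth = 30,
        readLength = 100L, insertMean = 400, insertSd = 40, seed = 7))
    n <- inversionCheck(aln, siteA, siteB)
    expect_gt(n, 0)
    ## truth: split reads with opposite-strand segments plus
    ## same-orientation pairs, all within the flanked interval
    rec <- aln$records
    splitQ <- unique(rec$qname[rec$category == "inversion_split" &
                               !rec$supp])
    tr <- aln$truth
    ffQ <- tr$qname[tr$strand1 == tr$strand2]
    expect_equal(n, length(splitQ) + length(ffQ))

    dels <- alleleSet(parent,
        list(list(list(type = "deletion", start = 18000L, end = 22000L)),
             list()))
    alnD <- simulateAlignments(dels, readSimConfig(depth = 30,
        readLength = 100L, insertMean = 400, insertSd = 40, seed = 8))
    expect_equal(inversionCheck(alnD, siteA, siteB), 0L)

    siteC <- targetSite("chr9", 25000L, 32L, "+", "AAG")
    expect_error(inversionCheck(aln, siteA, siteC), "one chromosome")
})
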