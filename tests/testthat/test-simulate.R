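test_that("genome simulation is seed-deterministic with controlled composition", {
    g1 <- simulateGenome(1000L, gc = 0.5, seed = 7)
    g2 <- simulateGenome(1000L, gc = 0.5, seed = 7)
    expect_identical(as.character(g1), as.character(g2))
    expect_false(identical(as.character(simulateGenome(1000L, 0.5, 8)),
                           as.character(g1)))

    at <- simulateGenome(10L, gc = 0, seed = 1)
    expect_false(grepl("[GC]", as.character(at[[1]])))

    g <- simulateGenome(100000L, gc = 0.41, seed = 3)
    obs <- sum(Biostrings::alphabetFrequency(g[[1]])[c("G", "C")]) / 100000
    expect_gte(obs, 0.395)   # binomial 3-sd band around 0.41
    expect_lte(obs, 0.425)

    expect_error(simulateGenome(0L), "positive")
})

test_that("plantProtospacer writes PAM and protospacer at the stated coordinates", {
    sp <- randomSpacer(5)
    g <- simulateGenome(10000L, seed = 2)
    pl <- plantProtospacer(g, sp, "AAG", 5000L, "+")
    s <- as.character(pl$genome[[1]])
    expect_equal(substr(s, 4998L, 5000L), "AAG")
    expect_equal(substr(s, 5001L, 5032L), sp)
    expect_equal(pl$target@pamStart, 4997L)

    pl2 <- plantProtospacer(g, sp, "AAG", 5000L, "-")
    s2 <- as.character(pl2$genome[[1]])
    block <- substr(s2, 5001L, 5035L)   # protospacer then PAM on forward
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(block)))
    expect_equal(rc, paste0("AAG", sp))

    expect_error(plantProtospacer(g, sp, "AAG", 9990L, "+"), "fit")
})

test_that("the deletion-size distribution is calibrated to its CDF anchors", {
    cal <- calibrateLogNormalSizes()
    expect_equal(plnorm(3000, cal["meanlog"], cal["sdlog"]),
                 0.565, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(plnorm(10000, cal["meanlog"], cal["sdlog"]),
                 0.864, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("Cas3 allele drawing respects rate, direction and bounds", {
    fix <- plantedFixture(50000L, 40000L)
    ## degenerate rate: nothing edited
    als0 <- simulateCas3Alleles(fix$genome, fix$target,
                                editConfig(editRate = 0, seed = 1), 20L)
    expect_true(all(vapply(alleleEdits(als0), length, 1L) == 0L))
    expect_equal(sum(alleleWeights(als0)), 1, tolerance = 1e-12)

    ## forced upstream on a + target: deletions entirely below the PAM
    als1 <- simulateCas3Alleles(fix$genome, fix$target,
        editConfig(editRate = 1, upstreamFraction = 1, seed = 2), 200L)
    dels <- do.call(rbind, lapply(alleleEdits(als1), function(e)
        if (length(e)) data.frame(s = e[[1]]$start, e = e[[1]]$end)))
    expect_true(all(dels$e <= fix$target@pamStart))
    expect_true(all(dels$s >= 0))

    ## mirrored on a - target: deletions entirely above the PAM end
    fixm <- plantedFixture(50000L, 8000L, strand = "-")
    alsm <- simulateCas3Alleles(fixm$genome, fixm$target,
        editConfig(editRate = 1, upstreamFraction = 1, seed = 3), 200L)
    delm <- do.call(rbind, lapply(alleleEdits(alsm), function(e)
        if (length(e)) data.frame(s = e[[1]]$start, e = e[[1]]$end)))
    expect_true(all(delm$s >= fixm$target@pamEnd))
    expect_true(all(delm$e <= 50000L))

    ## empirical size CDF at the 3-kb anchor (n = 10000 draws)
    big <- plantedFixture(1000000L, 950000L)
    alsn <- simulateCas3Alleles(big$genome, big$target,
        editConfig(editRate = 1, upstreamFraction = 1, seed = 4), 10000L)
    sz <- vapply(alleleEdits(alsn), function(e) e[[1]]$end - e[[1]]$start, 1L)
    expect_gte(mean(sz < 3000), 0.55)
    expect_lte(mean(sz < 3000), 0.58)
})

test_that("Cas9 alleles carry cut-site-centred indels", {
    sp20 <- randomSpacer(6, 20L)
    g <- simulateGenome(10000L, seed = 2)
    pl <- plantProtospacer(g, sp20, "CGG", 5000L, "+",
                           pamSide = "three_prime")
    cut <- pl$target@protoEnd - 3L
    als0 <- simulateCas9Alleles(pl$genome, pl$target, indelRate = 0,
                                nAlleles = 10L, seed = 1)
    expect_true(all(vapply(alleleEdits(als0), length, 1L) == 0L))

    als <- simulateCas9Alleles(pl$genome, pl$target, indelRate = 1,
                               nAlleles = 100L, seed = 2)
    for (e in alleleEdits(als)) {
        expect_length(e, 1L)
        expect_true(e[[1]]$start >= cut - 50L && e[[1]]$start <= cut + 50L)
        if (e[[1]]$type == "deletion")
            expect_lte(e[[1]]$end - e[[1]]$start, 50L)
    }
    ## a 1-bp insertion lengthens the allele by 1
    ins <- which(vapply(alleleEdits(als),
                        function(e) e[[1]]$type == "insertion" &&
                            nchar(e[[1]]$seq) == 1L, TRUE))[1]
    expect_equal(nchar(alleleSequence(als, ins)), 10001L)
})

test_that("alignment simulation is deterministic and evidence-sound at zero error", {
    fix <- plantedFixture(20000L, 15000L)
    unedited <- alleleSet(as.character(fix$genome[[1]]),
                          replicate(3, list(), simplify = FALSE))
    cfg <- readSimConfig(depth = 20, readLength = 100L, insertMean = 400,
                         insertSd = 40, seed = 11)
    a1 <- simulateAlignments(unedited, cfg)
    a2 <- simulateAlignments(unedited, cfg)
    expect_identical(a1$records, a2$records)

    ## no SV evidence without an SV
    ev <- classifyEvidence(a1, evidenceParams())
    expect_equal(nrow(ev), 0L)
    expect_true(all(a1$truth$proper))
})

test_that("breakpoint-crossing reads recover a planted deletion exactly", {
    fix <- plantedFixture(30000L, 25000L)
    als <- alleleSet(as.character(fix$genome[[1]]),
                     list(list(list(type = "deletion",
                                    start = 15000L, end = 20000L))))
    aln <- simulateAlignments(als, readSimConfig(depth = 30,
        readLength = 100L, insertMean = 400, insertSd = 40, seed = 3))
    rec <- aln$records
    spl <- rec[rec$category == "junction_split" & !rec$supp, ]
    expect_gt(nrow(spl), 0)
    ## every split read, via its SA pair, gives exactly [15000, 20000)
    calls <- callDeletionsNearTarget(aln,
        targetSite("chrS", 20100L, 32L, "+", "AAG"), flank = 1000L)
    expect_gt(nrow(calls), 0)
    expect_true(all(calls$start == 15000L))
    expect_true(all(calls$end == 20000L))
    expect_true(all(calls$size == 5000L))
    ## every deletion-spanning pair is discordant
    tr <- aln$truth
    spanning <- tr$span > 4000          # spans include the 5-kb gap
    expect_true(all(!tr$proper[spanning]))
})

test_that("discordant-pair counts match a fragment-geometry enumeration oracle", {
    fix <- plantedFixture(40000L, 30000L)
    parent <- as.character(fix$genome[[1]])
    als <- alleleSet(parent,
        list(list(list(type = "deletion", start = 20000L, end = 25000L)),
             list()),
        weights = c(0.3, 0.7))
    cfg <- readSimConfig(depth = 60, readLength = 100L, insertMean = 400,
                         insertSd = 40, seed = 21)
    aln <- simulateAlignments(als, cfg)
    ev <- classifyEvidence(aln, evidenceParams())
    nDisc <- sum(ev$type == "discordant")

    ## enumeration over the discretised fragment-length distribution
    totalFrag <- round(60 * 40000 / 200)
    lens <- 100:1000
    pl <- pnorm(lens + 0.5, 400, 40) - pnorm(lens - 0.5, 400, 40)
    pl <- pl / sum(pl)
    aLen <- 35000; jA <- 20000
    pCrossEdit <- sum(pl * (lens - 1) / (aLen - lens + 1))
    bound <- properPairBound(cfg)
    pLong <- sum(pl[lens > bound])      # non-crossing but over the bound
    expected <- totalFrag * (0.3 * pCrossEdit + pLong)
    expect_lt(abs(nDisc - expected), 3 * sqrt(expected))
})

test_that("short alleles are skipped with a warning", {
    g <- simulateGenome(30000L, seed = 4)
    als <- alleleSet(as.character(g[[1]]),
        list(list(list(type = "deletion", start = 100L, end = 29900L)),
             list()),
        weights = c(0.5, 0.5))
    expect_warning(
        simulateAlignments(als, readSimConfig(depth = 5, seed = 1)),
        "skipped")
})

test_that("amplicon depth reflects the retained-allele mixture", {
    g <- simulateGenome(20000L, seed = 5)
    parent <- as.character(g[[1]])
    flat <- alleleSet(parent, replicate(4, list(), simplify = FALSE))
    d0 <- simulateAmpliconDepth(flat, 5000L, 6000L, nominalDepth = 1000,
                                seed = NA)
    expect_true(all(d0$depth == 1000))

    mix <- alleleSet(parent,
        list(list(list(type = "deletion", start = 5200L, end = 5600L)),
             list(), list(), list()),
        weights = c(0.3, 0.3, 0.2, 0.2))
    d <- simulateAmpliconDepth(mix, 5000L, 6000L, nominalDepth = 2000,
                               seed = 8)
    inside <- d$depth[d$pos >= 5200 & d$pos < 5600]
    outside <- d$depth[d$pos < 5200 | d$pos >= 5600]
    expect_equal(mean(inside) / mean(outside), 0.7, tolerance = 0.03)

    expect_error(simulateAmpliconDepth(mix, -5L, 100L), "within")
})
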