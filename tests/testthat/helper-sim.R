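# Shared fixture builders.  Everything is generated in code at test time.

# hand-built evidence windows for score-arithmetic tests
.mkWindows <- function(split, disc) {
    gr <- GenomicRanges::GRanges("chrS",
        IRanges::IRanges(start = seq(1, by = 1000,
                                     length.out = length(split)),
                         width = 1000))
    S4Vectors::mcols(gr)$splitCount <- split
    S4Vectors::mcols(gr)$discordantCount <- disc
    gr
}

randomSpacer <- function(seed, L = 32L) {
    withr::with_seed(seed,
        paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""))
}

# a small genome with one planted type I-E protospacer
plantedFixture <- function(len = 20000L, pos = 15000L, strand = "+",
                           pam = "AAG", seed = 1L, spacerSeed = 9L) {
    sp <- randomSpacer(spacerSeed)
    g <- simulateGenome(len, gc = 0.41, seed = seed)
    pl <- plantProtospacer(g, sp, pam, pos, strand)
    list(genome = pl$genome, target = pl$target, spacer = sp)
}

# reference as a plain named character vector (oracle input)
refChar <- function(genome) {
    s <- as.character(genome)
    names(s) <- names(genome)
    s
}

# Detection-scale study condition: 2 x 100 bp at 60x, 600 +/- 60 bp
# inserts, background artifact rates tuned to ~40 split and ~40 discordant
# counts per 10-kb window per sample.
detectionReadConfig <- function(seed, depth = 60) {
    readSimConfig(readLength = 100L, insertMean = 600, insertSd = 60,
                  depth = depth, errorRate = 0,
                  noiseSplitRate = 40 / (depth * 10000 / 100),
                  noiseDiscRate = 40 / (depth * 10000 / 200),
                  seed = seed)
}

# Simulate one edited-vs-control pair under the detection condition and
# return the outlier-annotated PDD GRanges plus the target-window index.
# editRate = 0 gives the no-edit negative control.  Deletion sizes are
# held at 5 kb (sdlog ~ 0) and deletions forced PAM-upstream so that both
# breakpoints share the target window.
detectionPdd <- function(fix, seedBase, editRate = 0.3,
                         windowSize = 10000L, viaSam = FALSE) {
    len <- nchar(as.character(fix$genome[[1]]))
    ec <- editConfig(editRate = editRate, startOffsetMean = 217,
                     sizeMeanlog = log(5000), sizeSdlog = 1e-6,
                     upstreamFraction = 1, seed = seedBase)
    alsE <- simulateCas3Alleles(fix$genome, fix$target, ec, 200L)
    alsC <- alleleSet(as.character(fix$genome[[1]]),
                      replicate(200L, list(), simplify = FALSE),
                      parentName = names(fix$genome))
    samE <- if (viaSam) tempfile(fileext = ".sam") else NULL
    samC <- if (viaSam) tempfile(fileext = ".sam") else NULL
    alnE <- simulateAlignments(alsE, detectionReadConfig(seedBase + 1L),
                               samFile = samE)
    alnC <- simulateAlignments(alsC, detectionReadConfig(seedBase + 2L),
                               samFile = samC)
    ep <- evidenceParams(windowSize = windowSize)
    sl <- setNames(len, names(fix$genome))
    inE <- if (viaSam) samE else alnE
    inC <- if (viaSam) samC else alnC
    wE <- windowCounts(classifyEvidence(inE, ep), windowSize, sl)
    wC <- windowCounts(classifyEvidence(inC, ep), windowSize, sl)
    pdd <- computePdd(wE, wC, ep$minCount)
    pdd <- callPddOutliers(pdd, alpha = 0.05)
    if (viaSam) unlink(c(samE, samC))
    targetIdx <- which(GenomicRanges::start(pdd) - 1L <=
                           fix$target@pamStart &
                       GenomicRanges::end(pdd) >= fix$target@pamStart)
    list(pdd = pdd, targetIdx = targetIdx)
}
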