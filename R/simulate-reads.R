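## Paired-end alignment simulator.
##
## Reads are sampled from allele sequences and reported in parent-genome
## coordinates.  A read crossing a deletion junction is emitted as a primary
## soft-clipped alignment plus a supplementary alignment with an SA tag, so
## the breakpoint is recoverable exactly; deletions of at most
## .SMALL_INDEL_MAX bp are encoded aligner-style as CIGAR D operations and
## insertions as I operations.  Pairs whose reference span exceeds the
## proper-pair bound (insertMean + 4*insertSd) are flagged
## not-properly-paired.

.SMALL_INDEL_MAX <- 50L

.cig <- function(...) paste0(...)

## assemble one alignment record row
.rec <- function(qname, mate, pos0, cigar, refw, strand, seq, supp = FALSE,
                 category = "simple") {
    data.frame(qname = qname, mate = mate, pos0 = pos0, cigar = cigar,
               refw = refw, strand = strand, seq = seq, supp = supp,
               category = category, stringsAsFactors = FALSE)
}

## Generate primary (+ optional supplementary) records for all reads of one
## allele.  starts0/ends0 are allele-coordinate read intervals; native is
## TRUE for second mates (sequenced on the reverse strand).
.alleleReadRecords <- function(alleleIdx, eds, alleleSeq, parentLen,
                               starts0, rl, native, qnames) {
    starts0 <- as.integer(starts0)
    n <- length(starts0)
    ends0 <- starts0 + rl
    seqA <- substring(alleleSeq, starts0 + 1L, ends0)
    strandPlain <- ifelse(native, "-", "+")
    mate <- ifelse(native, 2L, 1L)

    simple <- function(pos0, category = "simple") {
        .rec(qnames, mate, pos0, .cig(rl, "M"), rep(rl, n), strandPlain,
             seqA, FALSE, category)
    }

    if (!length(eds)) {
        return(list(primary = simple(starts0), supp = NULL))
    }
    e <- eds[[1]]
    if (e$type == "deletion") {
        D1 <- e$start; D2 <- e$end; dl <- D2 - D1
        jA <- D1                       # junction in allele coordinates
        cross <- starts0 < jA & ends0 > jA
        posSimple <- starts0 + ifelse(starts0 >= jA, dl, 0L)
        prim <- simple(posSimple)
        supp <- NULL
        if (any(cross)) {
            idx <- which(cross)
            l <- jA - starts0[idx]
            r <- rl - l
            if (dl <= .SMALL_INDEL_MAX) {
                prim$pos0[idx] <- D1 - l
                prim$cigar[idx] <- .cig(l, "M", dl, "D", r, "M")
                prim$refw[idx] <- rl + dl
                prim$category[idx] <- "small_indel"
            } else {
                leftPrim <- l >= r
                prim$category[idx] <- "junction_split"
                prim$pos0[idx] <- ifelse(leftPrim, D1 - l, D2)
                prim$cigar[idx] <- ifelse(leftPrim,
                    .cig(l, "M", r, "S"), .cig(l, "S", r, "M"))
                prim$refw[idx] <- ifelse(leftPrim, l, r)
                supp <- .rec(qnames[idx], mate[idx],
                    ifelse(leftPrim, D2, D1 - l),
                    ifelse(leftPrim, .cig(l, "S", r, "M"),
                                     .cig(l, "M", r, "S")),
                    ifelse(leftPrim, r, l),
                    strandPlain[idx], seqA[idx], TRUE, "junction_split")
            }
        }
        return(list(primary = prim, supp = supp))
    }
    if (e$type == "insertion") {
        q0 <- e$start; k <- nchar(e$seq)
        if (k >= rl)
            stop("insertions must be shorter than the read length")
        ib0 <- q0; ib1 <- q0 + k      # inserted block in allele coords
        prim <- simple(starts0)
        before <- ends0 <= ib0
        after <- starts0 >= ib1
        prim$pos0[before] <- starts0[before]
        prim$pos0[after] <- starts0[after] - k
        contains <- starts0 < ib0 & ends0 > ib1
        if (any(contains)) {
            idx <- which(contains)
            a <- ib0 - starts0[idx]; b <- ends0[idx] - ib1
            prim$pos0[idx] <- starts0[idx]
            prim$cigar[idx] <- .cig(a, "M", k, "I", b, "M")
            prim$refw[idx] <- rl - k
            prim$category[idx] <- "small_indel"
        }
        endIn <- starts0 < ib0 & ends0 > ib0 & ends0 <= ib1
        if (any(endIn)) {
            idx <- which(endIn)
            x <- ends0[idx] - ib0
            prim$pos0[idx] <- starts0[idx]
            prim$cigar[idx] <- .cig(rl - x, "M", x, "S")
            prim$refw[idx] <- rl - x
            prim$category[idx] <- "small_indel"
        }
        startIn <- starts0 >= ib0 & starts0 < ib1 & ends0 > ib1
        if (any(startIn)) {
            idx <- which(startIn)
            x <- ib1 - starts0[idx]
            prim$pos0[idx] <- q0
            prim$cigar[idx] <- .cig(x, "S", rl - x, "M")
            prim$refw[idx] <- rl - x
            prim$category[idx] <- "small_indel"
        }
        return(list(primary = prim, supp = NULL))
    }
    if (e$type == "inversion") {
        I1 <- e$start; I2 <- e$end
        prim <- simple(starts0)
        suppRows <- list()
        ## reads fully inside the inverted block map reverse-complemented
        inside <- starts0 >= I1 & ends0 <= I2
        if (any(inside)) {
            idx <- which(inside)
            prim$pos0[idx] <- I1 + I2 - ends0[idx]
            prim$strand[idx] <- ifelse(strandPlain[idx] == "+", "-", "+")
            prim$seq[idx] <- .revcomp(seqA[idx])
            prim$category[idx] <- "inversion_inside"
        }
        crossing <- which((starts0 < I1 & ends0 > I1 & ends0 <= I2) |
                          (starts0 >= I1 & starts0 < I2 & ends0 > I2) |
                          (starts0 < I1 & ends0 > I2))
        for (i in crossing) {
            a0 <- starts0[i]; a1 <- ends0[i]
            segs <- list()
            if (a0 < I1)
                segs[[length(segs) + 1L]] <- list(
                    i1 = 1L, i2 = I1 - a0, pos0 = a0, O = "+")
            mid0 <- max(a0, I1); mid1 <- min(a1, I2)
            if (mid1 > mid0)
                segs[[length(segs) + 1L]] <- list(
                    i1 = mid0 - a0 + 1L, i2 = mid1 - a0,
                    pos0 = I1 + I2 - mid1, O = "-")
            if (a1 > I2)
                segs[[length(segs) + 1L]] <- list(
                    i1 = I2 - a0 + 1L, i2 = rl, pos0 = I2, O = "+")
            lens <- vapply(segs, function(s) s$i2 - s$i1 + 1L, 1L)
            ord <- order(lens, decreasing = TRUE)[1:2]
            mkrec <- function(s, supp) {
                m <- s$i2 - s$i1 + 1L
                alnStrand <- if (xor(native[i], s$O == "-")) "-" else "+"
                storedIsA <- s$O == "+"
                cb <- if (storedIsA) s$i1 - 1L else rl - s$i2
                ca <- rl - m - cb
                cigar <- paste0(if (cb) .cig(cb, "S") else "",
                                m, "M",
                                if (ca) .cig(ca, "S") else "")
                .rec(qnames[i], mate[i], s$pos0, cigar, m, alnStrand,
                     if (storedIsA) seqA[i] else .revcomp(seqA[i]),
                     supp, "inversion_split")
            }
            prim[i, ] <- mkrec(segs[[ord[1]]], FALSE)
            suppRows[[length(suppRows) + 1L]] <- mkrec(segs[[ord[2]]], TRUE)
        }
        supp <- if (length(suppRows)) do.call(rbind, suppRows) else NULL
        return(list(primary = prim, supp = supp))
    }
    stop("unsupported edit type: ", e$type)
}

#' Simulate paired-end alignments from an allele population
#'
#' Samples read pairs from the alleles of an [AlleleSet-class] and reports
#' them in parent-genome coordinates as SAM records (coordinate-sorted,
#' with header).  Structural-variant evidence is exact: split reads carry a
#' primary soft-clipped alignment plus a supplementary alignment with an SA
#' tag whose positions recover the breakpoint to the base pair; pairs whose
#' fragment spans a deletion have their template length inflated by the
#' deletion size and lose the properly-paired flag when the span exceeds
#' [properPairBound()].  Substitution errors (no indel errors) are applied
#' at \code{errorRate}; optional background noise adds artifactual soft
#' clips and chimeric distant pairs (see [ReadSimConfig-class]).
#'
#' @param alleles An [AlleleSet-class]; each allele may carry at most one
#'   edit event.
#' @param cfg A [ReadSimConfig-class].
#' @param samFile Optional path; when given, a valid SAM file is written.
#' @return An object of class `SimAlignments`: a list with `records`
#'   (data.frame of SAM fields plus truth columns `category` and `supp`),
#'   `truth` (per-pair data.frame: `qname`, `allele`, `span`,
#'   `proper`, `category1`, `category2`), `seqname`, `seqlength`, and
#'   `samFile`.
#' @examples
#' g <- simulateGenome(20000, seed = 1)
#' pl <- plantProtospacer(g, strrep("ACGT", 8), "AAG", 15000, "+")
#' als <- simulateCas3Alleles(pl$genome, pl$target,
#'     editConfig(editRate = 1, seed = 3), 4)
#' aln <- simulateAlignments(als, readSimConfig(depth = 10, seed = 4))
#' head(aln$truth)
#' @export
simulateAlignments <- function(alleles, cfg, samFile = NULL) {
    stopifnot(is(alleles, "AlleleSet"), is(cfg, "ReadSimConfig"))
    rl <- cfg@readLength
    parentLen <- nchar(alleles@parentSeq)
    seqname <- alleles@parentName
    nAll <- nAlleles(alleles)
    minLen <- cfg@insertMean + 4 * cfg@insertSd

    out <- .withSeed(cfg@seed, {
        totalFrag <- max(1L, round(cfg@depth * parentLen / (2 * rl)))
        nFrag <- as.vector(rmultinom(1L, totalFrag, alleles@weights))
        primList <- list(); suppList <- list(); truthList <- list()
        for (ai in seq_len(nAll)) {
            if (nFrag[ai] == 0L) next
            aseq <- alleleSequence(alleles, ai)
            aLen <- nchar(aseq)
            if (aLen < minLen) {
                warning(sprintf(
                    "allele %d (%d bp) shorter than insertMean + 4*insertSd; skipped",
                    ai, aLen))
                next
            }
            nf <- nFrag[ai]
            frag <- pmin(pmax(round(rnorm(nf, cfg@insertMean, cfg@insertSd)),
                              rl), aLen)
            fs0 <- floor(runif(nf) * (aLen - frag + 1))
            qn <- sprintf("a%04d_f%07d", ai, seq_len(nf))
            starts0 <- c(fs0, fs0 + frag - rl)
            native <- c(rep(FALSE, nf), rep(TRUE, nf))
            rr <- .alleleReadRecords(ai, alleles@edits[[ai]], aseq,
                                     parentLen, starts0, rl, native,
                                     c(qn, qn))
            rr$primary$allele <- ai
            if (!is.null(rr$supp)) rr$supp$allele <- ai
            primList[[length(primList) + 1L]] <- rr$primary
            suppList[[length(suppList) + 1L]] <- rr$supp
        }
        prim <- do.call(rbind, primList)
        supp <- if (length(suppList)) do.call(rbind, suppList) else NULL

        ## ---- background noise -------------------------------------------
        simpleIdx <- which(prim$category == "simple")
        if (cfg@noiseDiscRate > 0) {
            ## reposition the second mate of selected all-simple pairs
            m2 <- simpleIdx[prim$mate[simpleIdx] == 2L]
            qSimple1 <- prim$qname[simpleIdx[prim$mate[simpleIdx] == 1L &
                prim$category[simpleIdx] == "simple"]]
            m2 <- m2[prim$qname[m2] %in% qSimple1]
            pick <- m2[runif(length(m2)) < cfg@noiseDiscRate]
            if (length(pick)) {
                ## chimeric mate placed to the right, so the pair is still
                ## counted (leftmost mate) in its window of origin and the
                ## background rate stays uniform across windows
                d <- round(runif(length(pick), 2000,
                                 max(2001, min(50000, parentLen - rl - 1))))
                newPos <- pmin(pmax(prim$pos0[pick] + d, 0L),
                               parentLen - rl)
                prim$pos0[pick] <- newPos
                prim$seq[pick] <- substring(alleles@parentSeq,
                                            newPos + 1L, newPos + rl)
                prim$category[pick] <- "noise_disc"
            }
        }
        simpleIdx <- which(prim$category == "simple")
        if (cfg@noiseSplitRate > 0 && length(simpleIdx)) {
            pick <- simpleIdx[runif(length(simpleIdx)) < cfg@noiseSplitRate]
            if (length(pick)) {
                x <- sample(20:60, length(pick), TRUE)
                lead <- runif(length(pick)) < 0.5
                prim$cigar[pick] <- ifelse(lead,
                    .cig(x, "S", rl - x, "M"), .cig(rl - x, "M", x, "S"))
                prim$pos0[pick] <- prim$pos0[pick] + ifelse(lead, x, 0L)
                prim$refw[pick] <- rl - x
                prim$category[pick] <- "noise_split"
            }
        }

        ## ---- sequencing errors (substitutions only) ---------------------
        if (cfg@errorRate > 0) {
            nb <- nchar(prim$seq)
            nerr <- rbinom(1L, sum(nb), cfg@errorRate)
            if (nerr > 0L) {
                ri <- sample.int(nrow(prim), nerr, replace = TRUE, prob = nb)
                for (k in seq_len(nerr)) {
                    i <- ri[k]
                    p <- sample.int(nb[i], 1L)
                    old <- substr(prim$seq[i], p, p)
                    substr(prim$seq[i], p, p) <-
                        sample(setdiff(c("A", "C", "G", "T"), old), 1L)
                }
            }
        }
        list(prim = prim, supp = supp)
    })
    prim <- out$prim; supp <- out$supp

    ## ---- pair bookkeeping: flags, mate fields, TLEN ----------------------
    o1 <- prim$mate == 1L
    p1 <- prim[o1, ]; p2 <- prim[!o1, ]
    p2 <- p2[match(p1$qname, p2$qname), ]
    stopifnot(!anyNA(p2$qname))
    end1 <- p1$pos0 + p1$refw; end2 <- p2$pos0 + p2$refw
    span <- pmax(end1, end2) - pmin(p1$pos0, p2$pos0)
    bound <- properPairBound(cfg)
    fr <- (p1$strand != p2$strand) &
        ifelse(p1$strand == "+", p1$pos0 <= p2$pos0, p2$pos0 <= p1$pos0)
    proper <- fr & span <= bound
    firstLeft <- p1$pos0 < p2$pos0 | (p1$pos0 == p2$pos0)
    tlen1 <- ifelse(firstLeft, span, -span)

    pairInfo <- data.frame(qname = p1$qname, allele = p1$allele,
        span = span, proper = proper,
        category1 = p1$category, category2 = p2$category,
        pos1 = p1$pos0, pos2 = p2$pos0,
        strand1 = p1$strand, strand2 = p2$strand,
        stringsAsFactors = FALSE)

    mkflag <- function(df, mateDf, first, properVec) {
        1L +
            ifelse(properVec, 2L, 0L) +
            ifelse(df$strand == "-", 16L, 0L) +
            ifelse(mateDf$strand == "-", 32L, 0L) +
            (if (first) 64L else 128L)
    }
    rows <- function(df, mateDf, first, properVec, tlen, sa = NA_character_) {
        data.frame(qname = df$qname,
            flag = mkflag(df, mateDf, first, properVec),
            pos = df$pos0 + 1L, cigar = df$cigar,
            pnext = mateDf$pos0 + 1L, tlen = tlen, seq = df$seq,
            sa = sa, category = df$category, supp = df$supp,
            allele = df$allele, mate = df$mate, refw = df$refw,
            strand = df$strand, stringsAsFactors = FALSE)
    }
    ## SA tags between primary and supplementary of the same read
    saFor <- function(df)
        sprintf("%s,%d,%s,%s,60,0;", seqname, df$pos0 + 1L, df$strand,
                df$cigar)
    sa1 <- rep(NA_character_, nrow(p1)); sa2 <- rep(NA_character_, nrow(p2))
    supRows <- NULL
    if (!is.null(supp) && nrow(supp)) {
        key <- paste(supp$qname, supp$mate)
        k1 <- match(paste(p1$qname, 1L), key)
        k2 <- match(paste(p2$qname, 2L), key)
        sa1[!is.na(k1)] <- saFor(supp[k1[!is.na(k1)], ])
        sa2[!is.na(k2)] <- saFor(supp[k2[!is.na(k2)], ])
        ## supplementary records reference their primary
        pk <- ifelse(supp$mate == 1L,
                     match(supp$qname, p1$qname), match(supp$qname, p2$qname))
        primOfSupp <- ifelse(supp$mate == 1L,
                             saFor(p1)[pk], saFor(p2)[pk])
        mateDf <- data.frame(
            pos0 = ifelse(supp$mate == 1L, p2$pos0[pk], p1$pos0[pk]),
            strand = ifelse(supp$mate == 1L, p2$strand[pk], p1$strand[pk]),
            stringsAsFactors = FALSE)
        supProper <- proper[pk]
        supRows <- data.frame(qname = supp$qname,
            flag = 1L + ifelse(supProper, 2L, 0L) +
                ifelse(supp$strand == "-", 16L, 0L) +
                ifelse(mateDf$strand == "-", 32L, 0L) +
                ifelse(supp$mate == 1L, 64L, 128L) + 2048L,
            pos = supp$pos0 + 1L, cigar = supp$cigar,
            pnext = mateDf$pos0 + 1L, tlen = 0L, seq = supp$seq,
            sa = primOfSupp, category = supp$category, supp = TRUE,
            allele = supp$allele, mate = supp$mate, refw = supp$refw,
            strand = supp$strand, stringsAsFactors = FALSE)
    }
    r1 <- rows(p1, p2, TRUE, proper, tlen1, sa1)
    r2 <- rows(p2, p1, FALSE, proper, -tlen1, sa2)
    records <- rbind(r1, r2, supRows)
    records <- records[order(records$pos, records$qname, records$supp), ]
    rownames(records) <- NULL

    res <- structure(list(records = records, truth = pairInfo,
                          seqname = seqname, seqlength = parentLen,
                          samFile = samFile, readLength = rl,
                          properBound = bound),
                     class = "SimAlignments")
    if (!is.null(samFile)) writeSimSam(res, samFile)
    res
}

#' Write simulated alignments as a SAM file
#'
#' Emits a coordinate-sorted SAM file (header with \code{@HD}/\code{@SQ})
#' from a `SimAlignments` object; supplementary alignments carry SA tags.
#' The output is valid against the SAM specification and round-trips
#' through Rsamtools.
#'
#' @param x A `SimAlignments` object from [simulateAlignments()].
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
writeSimSam <- function(x, path) {
    rec <- x$records
    qual <- strrep("I", nchar(rec$seq))
    opt <- ifelse(is.na(rec$sa), "", paste0("\tSA:Z:", rec$sa))
    lines <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s%s",
        rec$qname, rec$flag, x$seqname, rec$pos, rec$cigar, rec$pnext,
        rec$tlen, rec$seq, qual, opt)
    header <- c("@HD\tVN:1.6\tSO:coordinate",
                sprintf("@SQ\tSN:%s\tLN:%d", x$seqname, x$seqlength),
                "@PG\tID:cas3edit\tPN:cas3edit")
    writeLines(c(header, lines), path)
    invisible(path)
}
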