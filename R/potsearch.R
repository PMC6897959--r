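## Potential off-target (POT) site enumeration.
##
## The type I-E surveillance complex reads the 32-nt spacer in 6-nt
## increments; every sixth position is displaced by the Cas7 thumb and
## cannot base-pair with the target, so the search treats positions 6, 12,
## 18, 24 and 30 as automatic matches.  Two matching rules are supported:
## the maximal run of PAM-proximal consecutive matches ("consecutive"
## mode) and the total mismatch count over the 27 read positions
## ("mismatch" mode).  Candidate loci must carry a PAM from the query's
## PAM set immediately PAM-side of the protospacer; reference ambiguity
## codes never match anything, including PAM bases.

## Core scanner for one strand of one sequence.
## chars: reference as a character vector; pattern: protospacer pattern in
## FORWARD reference orientation; wildcard: logical per pattern position;
## pamLeft: PAM window sits immediately left of the protospacer window;
## pamSet: PAMs in forward reference orientation; proximalLeft: pattern
## index 1 is the PAM-proximal spacer position (TRUE) or index L is
## (FALSE).
.scanStrand <- function(chars, pattern, wildcard, pamSet, pamLeft,
                        proximalLeft) {
    n <- length(chars)
    L <- length(pattern)
    if (n < L + 3L)
        return(data.frame(start0 = integer(), runLen = integer(),
                          mmCount = integer()))
    starts <- seq_len(n - L + 1L)          # 1-based protospacer starts
    pamStart0 <- if (pamLeft) starts - 4L else starts + L - 1L
    pamOK <- rep(FALSE, length(starts))
    for (p in pamSet)
        pamOK <- pamOK | .pamMatches(chars, pamStart0, p)
    keep <- which(pamOK)
    if (!length(keep))
        return(data.frame(start0 = integer(), runLen = integer(),
                          mmCount = integer()))
    ## positionwise match vectors over surviving starts
    ord <- if (proximalLeft) seq_len(L) else rev(seq_len(L))
    alive <- rep(TRUE, length(keep))
    runLen <- integer(length(keep))
    mm <- integer(length(keep))
    for (j in seq_len(L)) {
        jj <- ord[j]                        # proximal rank j -> pattern index
        base <- chars[keep + jj - 1L]
        mj <- if (wildcard[jj]) base %in% c("A", "C", "G", "T")
              else base == pattern[jj]
        runLen <- runLen + (alive & mj)
        alive <- alive & mj
        ## wildcard positions fail only on ambiguity codes, which count as
        ## mismatches too (ambiguity never matches anything)
        mm <- mm + !mj
    }
    data.frame(start0 = keep - 1L, runLen = runLen, mmCount = mm)
}

## shared driver over a multi-sequence reference and both strands
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
.potScan <- function(genome, q) {
    spacer <- q@spacer
    if (!.validDna(spacer)) stop("spacer must be an ACGT string")
    L <- nchar(spacer)
    wc <- rep(FALSE, L)
    wc[wildcardPositions(q)] <- TRUE
    ref <- .asReference(genome)
    pamLeftPlus <- q@pamSide == "five_prime"   # 5' PAM: left of a + site

    hits <- list()
    for (sn in names(ref)) {
        chars <- .chars(ref[[sn]])
        n <- length(chars)
        ## + strand: pattern = spacer as written
        fw <- .scanStrand(chars, .chars(spacer), wc, q@pamSet,
                          pamLeft = pamLeftPlus, proximalLeft = pamLeftPlus)
        if (nrow(fw)) { fw$strand <- "+"; fw$chrom <- sn }
        ## - strand: pattern = revcomp(spacer), wildcards mirrored, PAMs
        ## revcomped, PAM window on the opposite side
        rcPat <- .chars(.revcomp(spacer))
        rv <- .scanStrand(chars, rcPat, rev(wc), .revcomp(q@pamSet),
                          pamLeft = !pamLeftPlus,
                          proximalLeft = !pamLeftPlus)
        if (nrow(rv)) { rv$strand <- "-"; rv$chrom <- sn }
        hits[[length(hits) + 1L]] <- rbind(fw, rv)
    }
    h <- do.call(rbind, hits)
    h$seqlen <- nchar(ref)[match(h$chrom, names(ref))]
    h$L <- L
    h
}

.potGRanges <- function(h, q) {
    L <- if (nrow(h)) h$L[1] else nchar(q@spacer)
    pamLeft <- ifelse(h$strand == "+", q@pamSide == "five_prime",
                      q@pamSide != "five_prime")
    pam0 <- ifelse(pamLeft, h$start0 - 3L, h$start0 + L)
    keep <- pam0 >= 0L & pam0 + 3L <= h$seqlen &
        h$start0 >= 0L & h$start0 + L <= h$seqlen
    h <- h[keep, ]; pam0 <- pam0[keep]
    gr <- GRanges(h$chrom, IRanges(start = h$start0 + 1L, width = L),
                  strand = h$strand)
    mcols(gr)$pamObserved <- h$pamObserved
    mcols(gr)$consecutiveMatchLen <- h$runLen
    mcols(gr)$mismatchCount <- h$mmCount
    gr[order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr), as.character(GenomicRanges::strand(gr)))]
}

## observed genomic PAM in spacer orientation for each hit row
.observedPam <- function(h, ref, q) {
    L <- h$L
    pamLeft <- ifelse(h$strand == "+", q@pamSide == "five_prime",
                      q@pamSide != "five_prime")
    pam0 <- ifelse(pamLeft, h$start0 - 3L, h$start0 + L)
    fwd <- substring(ref[h$chrom], pam0 + 1L, pam0 + 3L)
    ifelse(h$strand == "+", fwd, .revcomp(fwd))
}

#' Find POT sites by consecutive PAM-proximal matching
#'
#' Enumerates every locus, on both strands, where a PAM from the query's
#' PAM set sits immediately PAM-side of a candidate protospacer and the
#' spacer matches the protospacer perfectly from position 1 (PAM-proximal)
#' through at least \code{minConsecutive} positions, with wildcard
#' positions always matching.  Each locus is reported once with its
#' maximal consecutive match length.
#'
#' @param genome Reference: `DNAStringSet`, `DNAString` or (named)
#'   character.
#' @param q A [SpacerQuery-class] with `mode == "consecutive"` and
#'   `minConsecutive` set.
#' @return A `GRanges` (1-based ranges; convert with [potReport()] for
#'   0-based BED) sorted by (chrom, start, strand), with metadata columns
#'   `pamObserved`, `consecutiveMatchLen` and `mismatchCount`.
#' @examples
#' g <- simulateGenome(5000, seed = 1)
#' sp <- strrep("ACGT", 8)
#' pl <- plantProtospacer(g, sp, "AAG", 3000, "+")
#' q <- spacerQuery(sp, mode = "consecutive", minConsecutive = 32)
#' findPotConsecutive(pl$genome, q)
#' @export
findPotConsecutive <- function(genome, q) {
    stopifnot(is(q, "SpacerQuery"))
    if (q@mode != "consecutive")
        stop("query mode must be 'consecutive'")
    ref <- .asReference(genome)
    h <- .potScan(ref, q)
    h <- h[h$runLen >= q@minConsecutive, , drop = FALSE]
    h$pamObserved <- .observedPam(h, ref, q)
    .potGRanges(h, q)
}

#' Find POT sites by mismatch counting
#'
#' Enumerates every PAM-anchored locus whose mismatch count over the
#' non-wildcard spacer positions (27 of 32 for the type I-E default) is at
#' most `maxMismatches`.
#'
#' @inheritParams findPotConsecutive
#' @param q A [SpacerQuery-class] with `mode == "mismatch"` and
#'   `maxMismatches` set (7 in the Cas3 reproduction settings).
#' @return A `GRanges` as in [findPotConsecutive()]; use
#'   [potMismatchPositions()] for per-site mismatch coordinates.
#' @export
findPotMismatch <- function(genome, q) {
    stopifnot(is(q, "SpacerQuery"))
    if (q@mode != "mismatch")
        stop("query mode must be 'mismatch'")
    ref <- .asReference(genome)
    h <- .potScan(ref, q)
    h <- h[h$mmCount <= q@maxMismatches, , drop = FALSE]
    h$pamObserved <- .observedPam(h, ref, q)
    .potGRanges(h, q)
}

#' Find Cas9 POT sites (3'-NGG by default)
#'
#' Every 20-mer with at most `maxMismatches` mismatches to the guide
#' (no wildcard positions) followed by a PAM from `pamSet` on its 3' side,
#' on both strands.
#'
#' @inheritParams findPotConsecutive
#' @param guide 20-nt guide sequence, 5' to 3'.
#' @param maxMismatches Maximum mismatches (4 in the reproduction
#'   settings).
#' @param pamSet PAM set (default `"NGG"`, the SpCas9 standard; the search
#'   PAM is configurable).
#' @return A `GRanges` as in [findPotConsecutive()].
#' @export
findPotCas9 <- function(genome, guide, maxMismatches = 4L,
                        pamSet = "NGG") {
    q <- spacerQuery(guide, pamSet = pamSet, pamSide = "three_prime",
                     wildcardPeriod = NA_integer_, mode = "mismatch",
                     maxMismatches = maxMismatches)
    findPotMismatch(genome, q)
}

#' Mismatch positions of sites against a query
#'
#' 1-based spacer positions (PAM-proximal numbering) at which each site
#' differs from the spacer; wildcard positions are never reported.
#'
#' @param sites `GRanges` from a POT search.
#' @param genome The reference the sites were found in.
#' @param q The [SpacerQuery-class] used.
#' @return A list of integer vectors, one per site.
#' @importFrom GenomicRanges seqnames start end strand
#' @export
potMismatchPositions <- function(sites, genome, q) {
    ref <- .asReference(genome)
    L <- nchar(q@spacer)
    wc <- wildcardPositions(q)
    sp <- .chars(q@spacer)
    lapply(seq_along(sites), function(i) {
        sn <- as.character(seqnames(sites)[i])
        s1 <- start(sites)[i]; e1 <- end(sites)[i]
        seq <- substring(ref[[sn]], s1, e1)
        if (as.character(strand(sites)[i]) == "-") seq <- .revcomp(seq)
        obs <- .chars(seq)
        mm <- which(obs != sp)
        setdiff(mm, wc)
    })
}

#' Tabulate and export POT sites
#'
#' Builds a per-site table (0-based half-open coordinates, strand, PAM,
#' match statistic, flanking sequence) plus a histogram of the match
#' statistic, and optionally writes TSV and BED files.
#'
#' @param sites `GRanges` from a POT search.
#' @param q The [SpacerQuery-class] used.
#' @param genome Optional reference for flanking-sequence extraction.
#' @param flank Flanking bp to report on each side (default 10).
#' @param tsv,bed Optional output paths.
#' @return A list with elements `table` (data.frame) and `histogram`
#'   (table of `consecutiveMatchLen` in consecutive mode, otherwise of
#'   `mismatchCount`).
#' @importFrom rtracklayer export
#' @export
potReport <- function(sites, q, genome = NULL, flank = 10L,
                      tsv = NULL, bed = NULL) {
    stat <- if (q@mode == "consecutive") "consecutiveMatchLen"
            else "mismatchCount"
    if (length(sites)) {
        df <- data.frame(
            chrom = as.character(seqnames(sites)),
            start = start(sites) - 1L,
            end = end(sites),
            strand = as.character(strand(sites)),
            pamObserved = mcols(sites)$pamObserved,
            stringsAsFactors = FALSE)
        df[[stat]] <- mcols(sites)[[stat]]
        if (!is.null(genome)) {
            ref <- .asReference(genome)
            lo <- pmax(df$start - flank, 0L)
            hi <- pmin(df$end + flank,
                       nchar(ref)[match(df$chrom, names(ref))])
            df$flanking <- substring(ref[df$chrom], lo + 1L, hi)
        }
    } else {
        df <- .emptySiteFrame()
        df[[stat]] <- integer()
    }
    hist <- table(df[[stat]])
    if (!is.null(tsv))
        write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(bed)) {
        if (length(sites)) {
            bedGr <- sites
            names(bedGr) <- sprintf("site%04d", seq_along(bedGr))
            mcols(bedGr) <- S4Vectors::DataFrame(
                name = names(bedGr), score = mcols(sites)[[stat]])
            rtracklayer::export(bedGr, bed, format = "BED")
        } else {
            file.create(bed)
        }
    }
    list(table = df, histogram = hist)
}
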