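## Target-proximal deletion calling and characterisation.

## annotate raw (chrom,start,end,readId) calls with size, start offset and
## direction relative to a target.  Offsets are measured from the target
## edge on the deletion's side (the PAM boundary for PAM-upstream
## deletions, the protospacer-distal edge for downstream ones); the sign is
## positive on the PAM-upstream side.
.annotateCalls <- function(df, target) {
    if (is.null(df) || !nrow(df)) {
        return(data.frame(chrom = character(), start = integer(),
            end = integer(), size = integer(), startOffset = integer(),
            direction = character(), readId = character(),
            stringsAsFactors = FALSE))
    }
    plus <- target@strand == "+"
    ## boundaries of the full PAM+protospacer block
    upEdge <- if (plus) target@pamStart else target@pamEnd
    downEdge <- if (plus) target@protoEnd else target@protoStart
    df$size <- df$end - df$start
    if (plus) {
        upstream <- df$end <= upEdge
        downstream <- df$start >= downEdge
        off <- ifelse(upstream, upEdge - df$end,
               ifelse(downstream, -(df$start - downEdge),
                      upEdge - df$end))
    } else {
        upstream <- df$start >= upEdge
        downstream <- df$end <= downEdge
        off <- ifelse(upstream, df$start - upEdge,
               ifelse(downstream, -(downEdge - df$end),
                      df$start - upEdge))
    }
    df$startOffset <- as.integer(off)
    df$direction <- ifelse(upstream, "upstream",
                    ifelse(downstream, "downstream", "spanning"))
    df[c("chrom", "start", "end", "size", "startOffset", "direction",
         "readId")]
}

#' Call deletions from split reads near a target site
#'
#' Emits one deletion call per split read whose breakpoint lies within
#' `flank` bp of the target site (PAM plus protospacer).  The deleted
#' interval is the reference gap between the read's two aligned segments
#' (left segment end to right segment start), reconstructed from the
#' primary alignment and its SA tag; calls are deduplicated per read.
#' Reads without a resolvable second segment on the same strand and
#' chromosome are skipped (count reported via attribute `nUnresolved`).
#'
#' @param x Alignments (path, `SimAlignments`, or data.frame; see
#'   [classifyEvidence()]).
#' @param target A [TargetSite-class].
#' @param flank Breakpoint window around the target in bp (default 1000).
#' @return A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `size`, `startOffset` (signed; positive PAM-upstream),
#'   `direction` (`upstream`/`downstream`/`spanning`) and `readId`.
#' @export
callDeletionsNearTarget <- function(x, target, flank = 1000L) {
    stopifnot(is(target, "TargetSite"))
    a <- .loadAlignments(x)
    flag <- a$flag
    primary <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L &
        bitwAnd(flag, 0x400L) == 0L & bitwAnd(flag, 0x4L) == 0L
    a <- a[primary & a$hasSA, , drop = FALSE]
    nUnresolved <- 0L
    rows <- NULL
    if (nrow(a)) {
        parts <- strsplit(sub(";.*$", "", a$sa), ",", fixed = TRUE)
        saChrom <- vapply(parts, `[`, "", 1L)
        saPos <- as.integer(vapply(parts, `[`, "", 2L))
        saStrand <- vapply(parts, `[`, "", 3L)
        saCigar <- vapply(parts, `[`, "", 4L)
        strand <- ifelse(bitwAnd(a$flag, 0x10L) == 16L, "-", "+")
        ok <- saChrom == a$rname & saStrand == strand &
            a$rname == target@seqname
        nUnresolved <- sum(saChrom != a$rname | saStrand != strand)
        if (any(ok)) {
            g1 <- .cigarGeom(a$cigar[ok])
            g2 <- .cigarGeom(saCigar[ok])
            p1 <- a$pos[ok]; p2 <- saPos[ok]
            leftFirst <- p1 <= p2
            ls <- ifelse(leftFirst, p1, p2)
            lw <- ifelse(leftFirst, g1$refw, g2$refw)
            rs <- ifelse(leftFirst, p2, p1)
            delStart <- ls - 1L + lw       # 0-based
            delEnd <- rs - 1L
            readId <- paste0(a$qname[ok], "/",
                ifelse(bitwAnd(a$flag[ok], 0x40L) == 64L, 1L, 2L))
            keep <- delEnd > delStart
            rows <- data.frame(chrom = a$rname[ok][keep],
                start = as.integer(delStart[keep]),
                end = as.integer(delEnd[keep]),
                readId = readId[keep], stringsAsFactors = FALSE)
            rows <- rows[!duplicated(rows$readId), , drop = FALSE]
            ## breakpoint within +/- flank of the target block
            lo <- min(target@protoStart, target@pamStart) - flank
            hi <- max(target@protoEnd, target@pamEnd) + flank
            nearby <- (rows$start >= lo & rows$start <= hi) |
                      (rows$end >= lo & rows$end <= hi)
            rows <- rows[nearby, , drop = FALSE]
        }
    }
    out <- .annotateCalls(rows, target)
    attr(out, "nUnresolved") <- nUnresolved
    out
}

#' Summarise a set of deletion calls
#'
#' Distribution summaries over unique deleted intervals (one vote per
#' distinct interval by default, since one molecule can yield many reads;
#' set `perRead = TRUE` to weight by supporting reads).  Quantiles use
#' linear interpolation (type 7).  Start-offset statistics use the offset
#' magnitude (distance from the target edge on the deletion's side).
#'
#' @param calls `data.frame` from [callDeletionsNearTarget()] or
#'   [allelesToCalls()].
#' @param sizeBins Sizes (bp) at which to report the CDF (default 3 kb and
#'   10 kb).
#' @param startThreshold Offset (bp) for the `fracStartWithin` field
#'   (default 500).
#' @param perRead Count every call instead of unique intervals.
#' @return A list: `nCalls`, `meanSize`, `maxSize`, `sizeQuantiles`
#'   (25/50/75/90%), `fracLt` (named by size bin), `fracStartWithin`,
#'   `fracUpstream`, `startOffsetMean`, `startOffsetP90`.
#' @importFrom stats quantile
#' @export
summarizeDeletions <- function(calls, sizeBins = c(3000, 10000),
                               startThreshold = 500, perRead = FALSE) {
    if (!nrow(calls)) {
        return(list(nCalls = 0L, meanSize = NA_real_, maxSize = NA_real_,
            sizeQuantiles = setNames(rep(NA_real_, 4),
                c("25%", "50%", "75%", "90%")),
            fracLt = setNames(rep(NA_real_, length(sizeBins)),
                paste0("lt", sizeBins)),
            fracStartWithin = NA_real_, fracUpstream = NA_real_,
            startOffsetMean = NA_real_, startOffsetP90 = NA_real_))
    }
    if (!perRead)
        calls <- calls[!duplicated(calls[c("chrom", "start", "end")]), ,
                       drop = FALSE]
    sz <- calls$size
    offMag <- abs(calls$startOffset)
    fracLt <- vapply(sizeBins, function(b) mean(sz < b), 0)
    list(nCalls = nrow(calls),
         meanSize = mean(sz),
         maxSize = max(sz),
         sizeQuantiles = quantile(sz, c(0.25, 0.5, 0.75, 0.9), type = 7),
         fracLt = setNames(fracLt, paste0("lt", sizeBins)),
         fracStartWithin = mean(offMag < startThreshold),
         fracUpstream = mean(calls$direction == "upstream"),
         startOffsetMean = mean(offMag),
         startOffsetP90 = unname(quantile(offMag, 0.9, type = 7)))
}

#' Coverage-ratio editing efficiency from an amplicon depth track
#'
#' Estimates the large-deletion editing efficiency as
#' \deqn{100 \times (1 - d_{edited} / d_{control})}
#' where \eqn{d_{edited}} is the depth at a probe inside the
#' deletion-accumulating (PAM-upstream) region, `editedOffset` bp from the
#' PAM boundary, and \eqn{d_{control}} the depth at a probe on the
#' opposite (unedited) side, `controlOffset` bp beyond the protospacer.
#' Probe depth is the mean over a `probeWidth`-bp window centred on the
#' probe.  The estimate is clamped to [0, 100]; note it measures the
#' fraction of alleles whose deletion covers the edited probe, which
#' understates the edit rate when start offsets exceed `editedOffset`.
#'
#' @param depth `data.frame` with columns `pos` (0-based) and `depth`
#'   (from [simulateAmpliconDepth()] or a real depth track).
#' @param target A [TargetSite-class].
#' @param editedOffset Probe offset on the deletion side (default 300 bp).
#' @param controlOffset Probe offset on the opposite side (default 300 bp;
#'   100 is also conventional).
#' @param probeWidth Smoothing window in bp (default 10).
#' @return A list: `method`, `value` (percent), `editedProbe`,
#'   `controlProbe` (0-based positions), `editedDepth`, `controlDepth`.
#' @export
ampliconEfficiency <- function(depth, target, editedOffset = 300L,
                               controlOffset = 300L, probeWidth = 10L) {
    stopifnot(is(target, "TargetSite"))
    plus <- target@strand == "+"
    editedProbe <- if (plus) target@pamStart - editedOffset
                   else target@pamEnd + editedOffset
    controlProbe <- if (plus) target@protoEnd + controlOffset
                    else target@protoStart - controlOffset
    probeDepth <- function(p) {
        w <- depth$pos >= p - probeWidth %/% 2L &
             depth$pos <= p + probeWidth %/% 2L
        if (!any(w)) stop("probe position ", p, " outside the depth track")
        mean(depth$depth[w])
    }
    dE <- probeDepth(editedProbe)
    dC <- probeDepth(controlProbe)
    if (dC <= 0) stop("control probe depth is zero")
    val <- 100 * (1 - dE / dC)
    list(method = "coverage_ratio",
         value = min(100, max(0, val)),
         editedProbe = editedProbe, controlProbe = controlProbe,
         editedDepth = dE, controlDepth = dC)
}

#' PDD-to-efficiency calibration
#'
#' A single-point linear calibration anchored on a locus with a known
#' capture-sequencing efficiency: `k = referenceEfficiency/referencePdd`
#' percent per PDD unit.  The shipped default anchor is an on-target locus
#' with PDD 5.24 and 16.1% editing efficiency.
#'
#' @param referencePdd Anchor PDD score.
#' @param referenceEfficiency Anchor efficiency in percent.
#' @return A list with `k`, `referencePdd`, `referenceEfficiency`.
#' @export
pddCalibration <- function(referencePdd = 5.24,
                           referenceEfficiency = 16.1) {
    stopifnot(referencePdd > 0, referenceEfficiency > 0)
    list(k = referenceEfficiency / referencePdd,
         referencePdd = referencePdd,
         referenceEfficiency = referenceEfficiency)
}

#' Convert a PDD score to an editing-efficiency estimate
#'
#' @param pdd PDD score(s), non-negative.
#' @param cal Calibration from [pddCalibration()].
#' @return Efficiency in percent, clamped to [0, 100].
#' @examples
#' pddToEfficiency(5.24)  # 16.1
#' pddToEfficiency(3.5)   # ~10.75
#' @export
pddToEfficiency <- function(pdd, cal = pddCalibration()) {
    stopifnot(all(pdd >= 0))
    pmin(100, pmax(0, cal$k * pdd))
}

#' Count inversion-supporting evidence between two target sites
#'
#' Counts reads whose split segments map in opposite orientations (the
#' hallmark of an inversion junction) with both segments within `flank` bp
#' of the interval between the two sites, plus discordant pairs whose
#' mates map in the same orientation across the interval.
#'
#' @param x Alignments (path, `SimAlignments` or data.frame).
#' @param siteA,siteB Two [TargetSite-class] objects on one chromosome.
#' @param flank Positional slack in bp (default 1000).
#' @return Integer count of inversion-supporting reads.
#' @export
inversionCheck <- function(x, siteA, siteB, flank = 1000L) {
    stopifnot(is(siteA, "TargetSite"), is(siteB, "TargetSite"))
    if (siteA@seqname != siteB@seqname)
        stop("sites must be on one chromosome")
    a <- .loadAlignments(x)
    flag <- a$flag
    primary <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L &
        bitwAnd(flag, 0x4L) == 0L
    a <- a[primary, , drop = FALSE]
    lo <- min(siteA@protoStart, siteB@protoStart) - flank
    hi <- max(siteA@protoEnd, siteB@protoEnd) + flank

    n <- 0L
    ## split segments on opposite strands
    withSA <- which(a$hasSA)
    if (length(withSA)) {
        parts <- strsplit(sub(";.*$", "", a$sa[withSA]), ",", fixed = TRUE)
        saPos <- as.integer(vapply(parts, `[`, "", 2L))
        saStrand <- vapply(parts, `[`, "", 3L)
        strand <- ifelse(bitwAnd(a$flag[withSA], 0x10L) == 16L, "-", "+")
        opp <- saStrand != strand &
            a$pos[withSA] >= lo & a$pos[withSA] <= hi &
            saPos >= lo & saPos <= hi
        n <- n + length(unique(a$qname[withSA][opp]))
    }
    ## same-orientation pairs spanning the interval
    paired <- bitwAnd(a$flag, 0x1L) == 1L
    first <- paired & bitwAnd(a$flag, 0x40L) == 64L
    sameOri <- (bitwAnd(a$flag, 0x10L) == 16L) ==
               (bitwAnd(a$flag, 0x20L) == 32L)
    ff <- first & sameOri & a$pos >= lo & a$pos <= hi &
        a$mpos >= lo & a$mpos <= hi
    n + sum(ff, na.rm = TRUE)
}
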