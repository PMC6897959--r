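## Genome-wide large-deletion signal from alignment evidence.
##
## Pipeline: classifyEvidence() -> windowCounts() per sample ->
## computePdd() -> callPddOutliers(); capture panels use
## captureSubtractionScore() instead of the ratio scores.

#' Evidence-extraction parameters
#'
#' @param minClip Minimum soft-clip (bp) to call a split read when no
#'   supplementary alignment is present (default 20).
#' @param discordantDistance Template-span threshold (bp) beyond which a
#'   pair is discordant (default 1000, matching a > 1 kb deletion focus).
#' @param windowSize Tiling window (bp; default 100000; capture panels use
#'   1000 or 10000).
#' @param minCount Minimum split and discordant count required in both
#'   samples for a window to be scored (default 20).
#' @return A named list of parameters.
#' @export
evidenceParams <- function(minClip = 20L, discordantDistance = 1000L,
                           windowSize = 100000L, minCount = 20L) {
    stopifnot(minClip > 0, discordantDistance > 0, windowSize > 0,
              minCount > 0)
    list(minClip = as.integer(minClip),
         discordantDistance = as.integer(discordantDistance),
         windowSize = as.integer(windowSize),
         minCount = as.integer(minCount))
}

## load alignment fields from a SAM/BAM path, a SimAlignments object, or a
## prepared data.frame
#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamFlag BamFile
.loadAlignments <- function(x) {
    if (is(x, "SimAlignments")) {
        r <- x$records
        return(data.frame(qname = r$qname, flag = r$flag,
            rname = x$seqname, pos = r$pos, cigar = r$cigar,
            mpos = r$pnext, isize = r$tlen,
            hasSA = !is.na(r$sa), sa = r$sa, stringsAsFactors = FALSE))
    }
    if (is.data.frame(x)) {
        if (is.null(x$sa)) x$sa <- NA_character_
        if (is.null(x$hasSA)) x$hasSA <- !is.na(x$sa)
        return(x)
    }
    if (is.character(x) && length(x) == 1L) {
        path <- x
        if (grepl("\\.sam$", path, ignore.case = TRUE)) {
            dest <- tempfile(fileext = "")
            path <- asBam(path, destination = dest, overwrite = TRUE,
                          indexDestination = FALSE)
        }
        p <- ScanBamParam(
            what = c("qname", "flag", "rname", "pos", "cigar", "mpos",
                     "isize"),
            tag = "SA")
        b <- scanBam(BamFile(path), param = p)[[1]]
        sa <- b$tag$SA
        if (is.null(sa)) sa <- rep(NA_character_, length(b$qname))
        return(data.frame(qname = b$qname, flag = b$flag,
            rname = as.character(b$rname), pos = b$pos, cigar = b$cigar,
            mpos = b$mpos, isize = b$isize,
            hasSA = !is.na(sa), sa = sa, stringsAsFactors = FALSE))
    }
    stop("unsupported alignment input: ", class(x)[1])
}

## reference width and clip geometry from CIGAR strings (vectorised)
#' @importFrom GenomicAlignments cigarWidthAlongReferenceSpace
.cigarGeom <- function(cigar) {
    refw <- cigarWidthAlongReferenceSpace(cigar)
    lead <- rep(0L, length(cigar))
    hasLead <- grepl("^[0-9]+S", cigar)
    lead[hasLead] <- as.integer(sub("^([0-9]+)S.*", "\\1", cigar[hasLead]))
    trail <- rep(0L, length(cigar))
    hasTrail <- grepl("[0-9]+S$", cigar)
    trail[hasTrail] <-
        as.integer(sub(".*?([0-9]+)S$", "\\1", cigar[hasTrail]))
    list(refw = refw, lead = lead, trail = trail)
}

#' Classify split-read and discordant-pair evidence
#'
#' A read is a split read iff it has a supplementary alignment (SA tag) or
#' a soft clip of at least `minClip` bp; it is counted once (primary record
#' only) at the clip/breakpoint position.  A pair is discordant iff it is
#' not flagged properly-paired or its template span exceeds
#' `discordantDistance`; it is counted once at the leftmost mate's
#' position.  Secondary alignments and duplicates are ignored.
#'
#' @param x Alignments: a SAM/BAM path, a `SimAlignments` object, or a
#'   data.frame with columns `qname`, `flag`, `rname`, `pos`, `cigar`,
#'   `mpos`, `isize`, `hasSA`.
#' @param params [evidenceParams()].
#' @return A `data.frame` of evidence items: `type` (`"split"` or
#'   `"discordant"`), `chrom`, `pos` (1-based), `qname`.
#' @export
classifyEvidence <- function(x, params = evidenceParams()) {
    a <- .loadAlignments(x)
    flag <- a$flag
    primary <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L &
        bitwAnd(flag, 0x400L) == 0L & bitwAnd(flag, 0x4L) == 0L
    a <- a[primary, , drop = FALSE]
    a$isize[is.na(a$isize)] <- 0L
    a$mpos[is.na(a$mpos)] <- a$pos[is.na(a$mpos)]
    if (!nrow(a))
        return(data.frame(type = character(), chrom = character(),
                          pos = integer(), qname = character(),
                          stringsAsFactors = FALSE))
    geom <- .cigarGeom(a$cigar)

    ## split reads: SA tag or long soft clip; breakpoint at the clip side
    isSplit <- a$hasSA | geom$lead >= params$minClip |
        geom$trail >= params$minClip
    clipLead <- geom$lead >= geom$trail
    splitPos <- ifelse(clipLead, a$pos, a$pos + geom$refw - 1L)
    sp <- data.frame(type = rep("split", sum(isSplit)),
                     chrom = a$rname[isSplit],
                     pos = as.integer(splitPos[isSplit]),
                     qname = a$qname[isSplit], stringsAsFactors = FALSE)

    ## discordant pairs: count once via the first-of-pair primary record
    paired <- bitwAnd(a$flag, 0x1L) == 1L
    if (!any(paired)) {
        if (nrow(a)) warning("unpaired data: discordant counts are zero")
        dc <- data.frame(type = character(), chrom = character(),
                         pos = integer(), qname = character(),
                         stringsAsFactors = FALSE)
    } else {
        first <- paired & bitwAnd(a$flag, 0x40L) == 64L
        proper <- bitwAnd(a$flag, 0x2L) == 2L
        disc <- first & (!proper | abs(a$isize) > params$discordantDistance)
        dc <- data.frame(type = rep("discordant", sum(disc)),
                         chrom = a$rname[disc],
                         pos = as.integer(pmin(a$pos[disc], a$mpos[disc])),
                         qname = a$qname[disc], stringsAsFactors = FALSE)
    }
    rbind(sp, dc)
}

#' Count evidence in tiling windows
#'
#' Tiles each reference sequence with non-overlapping windows
#' `[0, w), [w, 2w), ...` and counts split and discordant evidence per
#' window; every evidence item falls in exactly one window, so window sums
#' conserve the totals.
#'
#' @param evidence `data.frame` from [classifyEvidence()].
#' @param windowSize Window size in bp.
#' @param seqlengths Named integer vector of reference lengths.
#' @return A `GRanges` of windows with metadata columns `splitCount` and
#'   `discordantCount`.
#' @importFrom GenomicRanges tileGenome seqnames start
#' @importFrom GenomeInfoDb Seqinfo
#' @export
windowCounts <- function(evidence, windowSize, seqlengths) {
    si <- Seqinfo(names(seqlengths), as.integer(seqlengths))
    gr <- tileGenome(si, tilewidth = windowSize,
                     cut.last.tile.in.chrom = TRUE)
    splitCount <- integer(length(gr))
    discCount <- integer(length(gr))
    if (nrow(evidence)) {
        ## arithmetic binning: window index from 0-based position
        evidence <- evidence[evidence$chrom %in% names(seqlengths) &
            evidence$pos >= 1L &
            evidence$pos <= seqlengths[evidence$chrom], , drop = FALSE]
        nWin <- ceiling(seqlengths / windowSize)
        offset <- c(0, cumsum(nWin))[seq_along(seqlengths)]
        names(offset) <- names(seqlengths)
        idx <- offset[evidence$chrom] +
            (evidence$pos - 1L) %/% windowSize + 1L
        tb <- table(factor(idx[evidence$type == "split"],
                           levels = seq_along(gr)))
        splitCount <- as.integer(tb)
        tb <- table(factor(idx[evidence$type == "discordant"],
                           levels = seq_along(gr)))
        discCount <- as.integer(tb)
    }
    mcols(gr)$splitCount <- splitCount
    mcols(gr)$discordantCount <- discCount
    gr
}

.checkSameTiling <- function(edited, control) {
    if (length(edited) != length(control) ||
        !all(as.character(seqnames(edited)) == as.character(seqnames(control))) ||
        !all(start(edited) == start(control)))
        stop("edited and control window tilings differ")
}

#' Compute windowed PDD scores
#'
#' For each window surviving the minimum-count filter, the split score
#' (SS) is the ratio of edited to control split-read counts, the
#' discordant score (DS) the ratio of discordant-pair counts, and the
#' potential DNA degradation score PDD = SS * DS, with
#' `logPDD = log(PDD)` (natural log; the base is immaterial to the
#' downstream outlier test).  A window is removed before scoring if either
#' sample's split or discordant count falls below `minCount`
#' (`filterPolicy = "either"`, the default, which also guarantees no
#' division by zero); `filterPolicy = "control"` inspects only the control
#' sample.
#'
#' @param edited,control Window `GRanges` from [windowCounts()] over
#'   identical tilings.
#' @param minCount Minimum count threshold (default 20).
#' @param filterPolicy `"either"` or `"control"`.
#' @return A `GRanges` of surviving windows with metadata columns
#'   `splitE`, `splitC`, `discE`, `discC`, `SS`, `DS`, `PDD`, `logPDD`.
#' @export
computePdd <- function(edited, control, minCount = 20L,
                       filterPolicy = c("either", "control")) {
    filterPolicy <- match.arg(filterPolicy)
    .checkSameTiling(edited, control)
    se <- mcols(edited)$splitCount; sc <- mcols(control)$splitCount
    de <- mcols(edited)$discordantCount; dc <- mcols(control)$discordantCount
    keep <- if (filterPolicy == "either")
        se >= minCount & sc >= minCount & de >= minCount & dc >= minCount
    else sc >= minCount & dc >= minCount
    gr <- edited[keep]
    mcols(gr) <- NULL
    mcols(gr)$splitE <- se[keep]; mcols(gr)$splitC <- sc[keep]
    mcols(gr)$discE <- de[keep]; mcols(gr)$discC <- dc[keep]
    mcols(gr)$SS <- se[keep] / sc[keep]
    mcols(gr)$DS <- de[keep] / dc[keep]
    mcols(gr)$PDD <- mcols(gr)$SS * mcols(gr)$DS
    mcols(gr)$logPDD <- log(mcols(gr)$PDD)
    gr
}

#' Flag PDD outlier windows by the repeated Grubbs test
#'
#' Applies [grubbsRepeated()] to the log-PDD values of min-count-filtered
#' windows and annotates each window with its outlier status and removal
#' rank.  The result does not depend on record order.
#'
#' @param records `GRanges` from [computePdd()].
#' @param alpha Significance level (default 0.05).
#' @param side Sidedness (default `"one_sided_max"`: degradation inflates
#'   PDD).
#' @return The input `GRanges` with added metadata columns `outlier`
#'   (logical) and `grubbsRank` (integer, `NA` for non-outliers).
#' @export
callPddOutliers <- function(records, alpha = 0.05,
                            side = c("one_sided_max", "two_sided")) {
    side <- match.arg(side)
    res <- grubbsRepeated(mcols(records)$logPDD, alpha = alpha, side = side)
    out <- rep(FALSE, length(records))
    rank <- rep(NA_integer_, length(records))
    oi <- outlierIndices(res)
    out[oi] <- TRUE
    rank[oi] <- seq_along(oi)
    mcols(records)$outlier <- out
    mcols(records)$grubbsRank <- rank
    records
}

#' Capture-panel subtraction score
#'
#' Per-window difference of split-read counts, edited minus control
#' (may be negative); used for targeted capture panels where the ratio
#' scores are unstable.  No minimum-count filter is applied.
#'
#' @param edited,control Window `GRanges` from [windowCounts()] over
#'   identical tilings.
#' @return The edited `GRanges` with a metadata column `subtractionScore`.
#' @export
captureSubtractionScore <- function(edited, control) {
    .checkSameTiling(edited, control)
    gr <- edited
    mcols(gr) <- NULL
    mcols(gr)$splitE <- mcols(edited)$splitCount
    mcols(gr)$splitC <- mcols(control)$splitCount
    mcols(gr)$subtractionScore <-
        mcols(edited)$splitCount - mcols(control)$splitCount
    gr
}
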