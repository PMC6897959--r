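#' @import methods
#' @importFrom stats rnorm rbinom rexp rlnorm rpois qt qnorm setNames
#' @importFrom utils write.table head
NULL

.validDna <- function(x) nchar(x) > 0L && !grepl("[^ACGT]", x)

## ---------------------------------------------------------------------------
## TargetSite
## ---------------------------------------------------------------------------

#' Target site of a CRISPR effector on a reference sequence
#'
#' A \code{TargetSite} records the genomic placement of a protospacer and its
#' protospacer adjacent motif (PAM).  All coordinates are 0-based, half-open.
#' For the type I-E system the 3-nt PAM lies immediately 5' of the
#' protospacer in protospacer orientation: on the \code{+} strand the PAM
#' interval ends where the protospacer starts; on the \code{-} strand the PAM
#' interval starts where the protospacer ends.  For Cas9 (3' PAM) the
#' adjacency is mirrored.
#'
#' @slot seqname Reference sequence name.
#' @slot protoStart,protoEnd Protospacer interval (0-based, half-open).
#' @slot strand \code{"+"} or \code{"-"}; the strand on which the spacer
#'   reads 5' to 3' with position 1 PAM-proximal.
#' @slot pam The 3-nt PAM as written in spacer orientation.
#' @slot pamStart,pamEnd PAM interval on the reference (0-based, half-open).
#'
#' @seealso [targetSite()], [plantProtospacer()]
#' @export
setClass("TargetSite",
    representation(
        seqname   = "character",
        protoStart = "integer",
        protoEnd   = "integer",
        strand     = "character",
        pam        = "character",
        pamStart   = "integer",
        pamEnd     = "integer"
    )
)

setValidity("TargetSite", function(object) {
    msg <- character()
    if (length(object@strand) != 1L || !object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    if (object@protoEnd <= object@protoStart)
        msg <- c(msg, "protospacer interval is empty")
    if (object@pamEnd - object@pamStart != 3L)
        msg <- c(msg, "PAM interval must span 3 bp")
    if (!grepl("^[ACGT]{3}$", object@pam))
        msg <- c(msg, "pam must be a 3-nt ACGT string")
    adjacent <- isTRUE(object@pamEnd == object@protoStart) ||
        isTRUE(object@pamStart == object@protoEnd)
    if (!adjacent)
        msg <- c(msg, "PAM interval must be immediately adjacent to the protospacer")
    if (length(msg)) msg else TRUE
})

#' Construct a TargetSite
#'
#' @param seqname Reference sequence name.
#' @param protoStart Protospacer start, 0-based.
#' @param width Protospacer width (32 for type I-E, 20 for Cas9).
#' @param strand `"+"` or `"-"`.
#' @param pam 3-nt PAM in spacer orientation.
#' @param pamSide `"five_prime"` (type I-E) or `"three_prime"` (Cas9),
#'   i.e. on which side of the protospacer the PAM sits in spacer
#'   orientation.
#' @return A [TargetSite-class] object.
#' @examples
#' targetSite("chr1", 5000L, 32L, "+", "AAG")
#' @export
targetSite <- function(seqname, protoStart, width, strand = "+", pam = "AAG",
                       pamSide = c("five_prime", "three_prime")) {
    pamSide <- match.arg(pamSide)
    protoStart <- as.integer(protoStart)
    width <- as.integer(width)
    fivePrimeLeft <- (strand == "+") == (pamSide == "five_prime")
    if (fivePrimeLeft) {
        pamStart <- protoStart - 3L
    } else {
        pamStart <- protoStart + width
    }
    new("TargetSite", seqname = as.character(seqname),
        protoStart = protoStart, protoEnd = protoStart + width,
        strand = strand, pam = toupper(pam),
        pamStart = pamStart, pamEnd = pamStart + 3L)
}

setMethod("show", "TargetSite", function(object) {
    cat(sprintf("TargetSite %s:%d-%d (%s), PAM %s at %d-%d\n",
        object@seqname, object@protoStart, object@protoEnd, object@strand,
        object@pam, object@pamStart, object@pamEnd))
})

## ---------------------------------------------------------------------------
## SpacerQuery
## ---------------------------------------------------------------------------

#' crRNA/guide query for potential off-target search
#'
#' Describes one spacer (type I-E, 32 nt) or guide (Cas9, 20 nt) together
#' with its PAM set and the matching rule used by the POT search.  Spacer
#' position 1 is PAM-proximal.  For type I-E, every
#' \code{wildcardPeriod}-th position (6, 12, 18, 24, 30 by default) is not
#' read by the surveillance complex (the Cas7 thumb displaces it) and always
#' counts as a match.
#'
#' @slot spacer Spacer/guide sequence, 5' to 3', over ACGT.
#' @slot pamSet Character vector of 3-nt PAMs; entries may contain \code{N}
#'   (any base).
#' @slot pamSide \code{"five_prime"} or \code{"three_prime"}.
#' @slot wildcardPeriod Integer period of wildcard positions, or
#'   \code{NA_integer_} for none.
#' @slot mode \code{"consecutive"} or \code{"mismatch"}.
#' @slot minConsecutive Minimum PAM-proximal perfect-match run
#'   (consecutive mode).
#' @slot maxMismatches Maximum mismatches over non-wildcard positions
#'   (mismatch mode).
#' @seealso [spacerQuery()], [findPotConsecutive()], [findPotMismatch()]
#' @export
setClass("SpacerQuery",
    representation(
        spacer        = "character",
        pamSet        = "character",
        pamSide       = "character",
        wildcardPeriod = "integer",
        mode          = "character",
        minConsecutive = "integer",
        maxMismatches  = "integer"
    )
)

#' Default type I-E PAM set
#'
#' The six PAMs with detectable Cas3 activity in human cells:
#' AAG (strongest), TAG, AAC, GAG, AGG, ATG.
#' @export
CAS3_PAM_SET <- c("AAG", "TAG", "AAC", "GAG", "AGG", "ATG")

setValidity("SpacerQuery", function(object) {
    msg <- character()
    if (!.validDna(object@spacer))
        msg <- c(msg, "spacer must be a non-empty ACGT string")
    if (!all(grepl("^[ACGTN]{3}$", object@pamSet)))
        msg <- c(msg, "pamSet entries must be 3-nt strings over ACGTN")
    if (!object@pamSide %in% c("five_prime", "three_prime"))
        msg <- c(msg, "pamSide must be 'five_prime' or 'three_prime'")
    if (!object@mode %in% c("consecutive", "mismatch"))
        msg <- c(msg, "mode must be 'consecutive' or 'mismatch'")
    L <- nchar(object@spacer)
    if (!is.na(object@wildcardPeriod) &&
        (object@wildcardPeriod < 2L || object@wildcardPeriod > L))
        msg <- c(msg, "wildcardPeriod must be in [2, spacer length]")
    if (object@mode == "consecutive" &&
        (is.na(object@minConsecutive) || object@minConsecutive < 1L ||
         object@minConsecutive > L))
        msg <- c(msg, "minConsecutive must be in [1, spacer length]")
    if (object@mode == "mismatch" &&
        (is.na(object@maxMismatches) || object@maxMismatches < 0L ||
         object@maxMismatches > L))
        msg <- c(msg, "maxMismatches must be in [0, spacer length]")
    if (length(msg)) msg else TRUE
})

#' Construct a SpacerQuery
#'
#' @param spacer Spacer/guide sequence (character, ACGT).
#' @param pamSet PAM set; defaults to the six type I-E PAMs
#'   ([CAS3_PAM_SET]).  Entries may contain `N`.
#' @param pamSide Side of the PAM relative to the protospacer in spacer
#'   orientation; `"five_prime"` for type I-E, `"three_prime"` for Cas9.
#' @param wildcardPeriod Period of always-match positions (default 6 for
#'   type I-E); use `NA` for none.
#' @param mode `"consecutive"` or `"mismatch"`.
#' @param minConsecutive Threshold for consecutive mode (required there; no
#'   library default because the useful value is locus-specific).
#' @param maxMismatches Threshold for mismatch mode (the reproduction
#'   settings are 7 for Cas3 and 4 for Cas9).
#' @return A [SpacerQuery-class] object.
#' @examples
#' spacerQuery(strrep("ACGT", 8), mode = "mismatch", maxMismatches = 7)
#' @export
spacerQuery <- function(spacer, pamSet = CAS3_PAM_SET,
                        pamSide = c("five_prime", "three_prime"),
                        wildcardPeriod = 6L,
                        mode = c("consecutive", "mismatch"),
                        minConsecutive = NA_integer_,
                        maxMismatches = NA_integer_) {
    new("SpacerQuery", spacer = toupper(spacer),
        pamSet = toupper(pamSet), pamSide = match.arg(pamSide),
        wildcardPeriod = as.integer(wildcardPeriod),
        mode = match.arg(mode),
        minConsecutive = as.integer(minConsecutive),
        maxMismatches = as.integer(maxMismatches))
}

setMethod("show", "SpacerQuery", function(object) {
    cat(sprintf("SpacerQuery: %d-nt spacer, %s mode, PAM {%s} (%s)\n",
        nchar(object@spacer), object@mode,
        paste(object@pamSet, collapse = ","), object@pamSide))
    if (!is.na(object@wildcardPeriod))
        cat(sprintf("  wildcard positions: %s\n",
            paste(wildcardPositions(object), collapse = ",")))
})

#' Wildcard positions of a query
#'
#' 1-based spacer positions that always count as matches (multiples of the
#' wildcard period, up to the spacer length).
#' @param q A [SpacerQuery-class].
#' @return Integer vector (possibly empty).
#' @export
wildcardPositions <- function(q) {
    L <- nchar(q@spacer)
    if (is.na(q@wildcardPeriod)) return(integer())
    p <- seq.int(q@wildcardPeriod, L, by = q@wildcardPeriod)
    ## a terminal wildcard would make the PAM-distal end unconstrained but is
    ## formally allowed; positions beyond L are impossible by construction
    p[p <= L]
}

## ---------------------------------------------------------------------------
## EditConfig
## ---------------------------------------------------------------------------

#' Configuration of the Cas3 deletion model
#'
#' Generative model for Cas3-edited allele populations: a fraction
#' \code{editRate} of alleles carries one contiguous deletion whose
#' PAM-proximal breakpoint lies \code{offset} bp from the target edge
#' (offset drawn from an exponential with mean \code{startOffsetMean}, 217 bp
#' by default) and whose length is drawn from a log-normal calibrated so
#' that P(size < 3 kb) = 0.565 and P(size < 10 kb) = 0.864.  The deletion
#' extends to the PAM-upstream side with probability
#' \code{upstreamFraction}.
#'
#' @slot editRate Fraction of alleles edited, in [0,1].
#' @slot startOffsetMean Mean of the exponential start-offset distribution
#'   (bp).
#' @slot sizeMeanlog,sizeSdlog Log-normal parameters of the deletion-size
#'   distribution (bp scale).
#' @slot upstreamFraction Probability that a deletion extends PAM-upstream.
#' @slot seed Integer seed.
#' @seealso [editConfig()], [simulateCas3Alleles()],
#'   [calibrateLogNormalSizes()]
#' @export
setClass("EditConfig",
    representation(
        editRate        = "numeric",
        startOffsetMean = "numeric",
        sizeMeanlog     = "numeric",
        sizeSdlog       = "numeric",
        upstreamFraction = "numeric",
        seed            = "integer"
    )
)

setValidity("EditConfig", function(object) {
    msg <- character()
    if (object@editRate < 0 || object@editRate > 1)
        msg <- c(msg, "editRate must be in [0,1]")
    if (object@upstreamFraction < 0 || object@upstreamFraction > 1)
        msg <- c(msg, "upstreamFraction must be in [0,1]")
    if (object@startOffsetMean < 0)
        msg <- c(msg, "startOffsetMean must be non-negative")
    if (object@sizeSdlog <= 0)
        msg <- c(msg, "sizeSdlog must be positive")
    if (length(msg)) msg else TRUE
})

#' Solve log-normal parameters from two CDF anchors
#'
#' Closed-form two-point fit: given P(X < q1) = p1 and P(X < q2) = p2 for a
#' log-normal X, returns \code{meanlog} and \code{sdlog}.
#'
#' @param q1,q2 Quantile locations (bp), q2 > q1.
#' @param p1,p2 Target CDF values at q1 and q2.
#' @return Named numeric vector with elements `meanlog` and `sdlog`.
#' @examples
#' calibrateLogNormalSizes()  # the deletion-size default anchors
#' @export
calibrateLogNormalSizes <- function(q1 = 3000, q2 = 10000,
                                    p1 = 0.565, p2 = 0.864) {
    stopifnot(q2 > q1, p2 > p1, p1 > 0, p2 < 1)
    sdlog <- (log(q2) - log(q1)) / (qnorm(p2) - qnorm(p1))
    meanlog <- log(q1) - qnorm(p1) * sdlog
    c(meanlog = meanlog, sdlog = sdlog)
}

#' Construct an EditConfig
#'
#' @param editRate Edited-allele fraction (default 0.3, a typical Cas3
#'   large-deletion efficiency at an active locus).
#' @param startOffsetMean Mean PAM-proximal breakpoint offset in bp
#'   (default 217).
#' @param sizeMeanlog,sizeSdlog Deletion-size log-normal parameters;
#'   defaults are solved from the 56.5%/3 kb and 86.4%/10 kb anchors via
#'   [calibrateLogNormalSizes()].
#' @param upstreamFraction Probability of PAM-upstream extension
#'   (default 0.95).
#' @param seed Integer seed.
#' @return An [EditConfig-class] object.
#' @export
editConfig <- function(editRate = 0.3, startOffsetMean = 217,
                       sizeMeanlog = NULL, sizeSdlog = NULL,
                       upstreamFraction = 0.95, seed = 1L) {
    if (is.null(sizeMeanlog) || is.null(sizeSdlog)) {
        cal <- calibrateLogNormalSizes()
        if (is.null(sizeMeanlog)) sizeMeanlog <- cal[["meanlog"]]
        if (is.null(sizeSdlog)) sizeSdlog <- cal[["sdlog"]]
    }
    new("EditConfig", editRate = editRate, startOffsetMean = startOffsetMean,
        sizeMeanlog = sizeMeanlog, sizeSdlog = sizeSdlog,
        upstreamFraction = upstreamFraction, seed = as.integer(seed))
}

setMethod("show", "EditConfig", function(object) {
    cat(sprintf(
        "EditConfig: editRate=%.3g, offset~Exp(mean=%g bp), size~LogNormal(%.4g, %.4g), upstream=%.3g, seed=%d\n",
        object@editRate, object@startOffsetMean, object@sizeMeanlog,
        object@sizeSdlog, object@upstreamFraction, object@seed))
})

## ---------------------------------------------------------------------------
## ReadSimConfig
## ---------------------------------------------------------------------------

#' Configuration of the paired-end read simulator
#'
#' Defaults mirror a 2 x 150 bp, 90x, ~450-bp-insert whole-genome library.
#' \code{noiseSplitRate} (per read) and \code{noiseDiscRate} (per pair)
#' inject background soft-clip and chimeric-pair artifacts; both default to
#' 0 so that at zero error every evidence record is attributable to a
#' planted edit.
#'
#' @slot readLength Read length (bp).
#' @slot insertMean,insertSd Fragment-length mean and sd (bp).
#' @slot depth Mean coverage.
#' @slot errorRate Per-base substitution probability.
#' @slot noiseSplitRate Per-read probability of an artifactual soft clip.
#' @slot noiseDiscRate Per-pair probability of an artifactual distant mate.
#' @slot seed Integer seed.
#' @seealso [readSimConfig()], [simulateAlignments()]
#' @export
setClass("ReadSimConfig",
    representation(
        readLength = "integer",
        insertMean = "numeric",
        insertSd   = "numeric",
        depth      = "numeric",
        errorRate  = "numeric",
        noiseSplitRate = "numeric",
        noiseDiscRate  = "numeric",
        seed       = "integer"
    )
)

setValidity("ReadSimConfig", function(object) {
    msg <- character()
    if (object@readLength < 30L)
        msg <- c(msg, "readLength must be >= 30")
    if (object@insertMean <= object@readLength)
        msg <- c(msg, "insertMean must exceed readLength")
    if (object@depth <= 0)
        msg <- c(msg, "depth must be positive")
    if (object@errorRate < 0 || object@errorRate > 0.5)
        msg <- c(msg, "errorRate must be in [0, 0.5]")
    if (object@noiseSplitRate < 0 || object@noiseSplitRate > 1 ||
        object@noiseDiscRate < 0 || object@noiseDiscRate > 1)
        msg <- c(msg, "noise rates must be in [0,1]")
    if (length(msg)) msg else TRUE
})

#' Construct a ReadSimConfig
#'
#' @param readLength Read length in bp (default 150).
#' @param insertMean,insertSd Fragment length mean/sd in bp (450/50).
#' @param depth Mean coverage (default 90).
#' @param errorRate Per-base substitution rate (default 0).
#' @param noiseSplitRate,noiseDiscRate Background artifact rates
#'   (default 0; see class docs).
#' @param seed Integer seed.
#' @return A [ReadSimConfig-class] object.
#' @export
readSimConfig <- function(readLength = 150L, insertMean = 450,
                          insertSd = 50, depth = 90, errorRate = 0,
                          noiseSplitRate = 0, noiseDiscRate = 0,
                          seed = 1L) {
    new("ReadSimConfig", readLength = as.integer(readLength),
        insertMean = insertMean, insertSd = insertSd, depth = depth,
        errorRate = errorRate, noiseSplitRate = noiseSplitRate,
        noiseDiscRate = noiseDiscRate, seed = as.integer(seed))
}

#' Proper-pair span bound of a read-sim configuration
#'
#' Pairs whose reference span exceeds `insertMean + 4 * insertSd` are
#' flagged not-properly-paired, matching the downstream 1-kb discordance
#' threshold at default settings.
#' @param cfg A [ReadSimConfig-class].
#' @return Numeric bound in bp.
#' @export
properPairBound <- function(cfg) cfg@insertMean + 4 * cfg@insertSd

setMethod("show", "ReadSimConfig", function(object) {
    cat(sprintf(
        "ReadSimConfig: 2x%d bp, insert %g+/-%g, depth %gx, error %.3g, noise split/disc %.3g/%.3g, seed %d\n",
        object@readLength, object@insertMean, object@insertSd, object@depth,
        object@errorRate, object@noiseSplitRate, object@noiseDiscRate,
        object@seed))
})

## ---------------------------------------------------------------------------
## AlleleSet
## ---------------------------------------------------------------------------

#' A weighted population of edited alleles over one parent sequence
#'
#' Each allele carries zero or more edits applied to the shared parent
#' sequence.  An edit is a list with fields \code{type} (one of
#' \code{"deletion"}, \code{"insertion"}, \code{"inversion"}),
#' \code{start}/\code{end} (0-based half-open parent interval; insertions
#' use \code{start} as the insertion point) and, for insertions,
#' \code{seq}.  Weights are allele population fractions and must sum to 1.
#'
#' @slot parentName Name of the parent sequence.
#' @slot parentSeq Parent sequence (character, ACGT).
#' @slot edits List (one element per allele) of lists of edits; an
#'   unedited allele has an empty edit list.
#' @slot weights Numeric allele fractions summing to 1.
#' @seealso [alleleSet()], [simulateCas3Alleles()], [alleleSequence()]
#' @export
setClass("AlleleSet",
    representation(
        parentName = "character",
        parentSeq  = "character",
        edits      = "list",
        weights    = "numeric"
    )
)

setValidity("AlleleSet", function(object) {
    msg <- character()
    if (length(object@edits) != length(object@weights))
        msg <- c(msg, "edits and weights lengths differ")
    if (length(object@weights) &&
        abs(sum(object@weights) - 1) > 1e-9)
        msg <- c(msg, "weights must sum to 1 (tolerance 1e-9)")
    if (any(object@weights < 0))
        msg <- c(msg, "weights must be non-negative")
    L <- nchar(object@parentSeq)
    for (al in object@edits) {
        for (e in al) {
            if (!e$type %in% c("deletion", "insertion", "inversion")) {
                msg <- c(msg, sprintf("unknown edit type '%s'", e$type))
                next
            }
            if (e$type == "insertion") {
                if (e$start < 0 || e$start > L)
                    msg <- c(msg, "insertion point out of bounds")
            } else if (e$start < 0 || e$end > L || e$end <= e$start) {
                msg <- c(msg, "edit interval out of genome bounds")
            }
        }
    }
    if (length(msg)) unique(msg) else TRUE
})

#' Construct an AlleleSet
#'
#' @param parentSeq Parent sequence (character or `DNAString`).
#' @param edits List of per-allele edit lists (see
#'   [AlleleSet-class]).
#' @param weights Allele fractions; default uniform.
#' @param parentName Sequence name (default `"chrS"`).
#' @return An [AlleleSet-class] object.
#' @export
alleleSet <- function(parentSeq, edits, weights = NULL,
                      parentName = "chrS") {
    parentSeq <- as.character(parentSeq)
    if (is.null(weights))
        weights <- rep(1 / length(edits), length(edits))
    new("AlleleSet", parentName = parentName, parentSeq = parentSeq,
        edits = edits, weights = weights)
}

#' Number of alleles in an AlleleSet
#' @param x An [AlleleSet-class].
#' @return Integer count.
#' @export
nAlleles <- function(x) length(x@edits)

#' Allele weights
#' @param x An [AlleleSet-class].
#' @return Numeric vector of population fractions.
#' @export
alleleWeights <- function(x) x@weights

#' Per-allele edit lists
#' @param x An [AlleleSet-class].
#' @return List of per-allele edit lists.
#' @export
alleleEdits <- function(x) x@edits

setMethod("show", "AlleleSet", function(object) {
    ne <- sum(vapply(object@edits, length, 1L) > 0L)
    cat(sprintf("AlleleSet: %d alleles over %s (%d bp), %d edited\n",
        length(object@edits), object@parentName,
        nchar(object@parentSeq), ne))
})

## ---------------------------------------------------------------------------
## GrubbsResult
## ---------------------------------------------------------------------------

#' Result of a repeated Grubbs outlier test
#'
#' @slot values The input vector.
#' @slot outlierIndices Indices into \code{values}, ordered by removal
#'   (most extreme first).
#' @slot gStatistics G statistic of each removed value at its removal step.
#' @slot criticalValues Grubbs critical value at each removal step.
#' @slot alpha Significance level.
#' @slot side \code{"one_sided_max"} or \code{"two_sided"}.
#' @seealso [grubbsRepeated()]
#' @export
setClass("GrubbsResult",
    representation(
        values = "numeric",
        outlierIndices = "integer",
        gStatistics = "numeric",
        criticalValues = "numeric",
        alpha = "numeric",
        side = "character"
    )
)

setMethod("show", "GrubbsResult", function(object) {
    cat(sprintf(
        "GrubbsResult: %d values, %d outlier(s) at alpha=%g (%s)\n",
        length(object@values), length(object@outlierIndices),
        object@alpha, object@side))
    if (length(object@outlierIndices))
        cat(sprintf("  removed (in order): %s\n",
            paste(signif(object@values[object@outlierIndices], 5),
                  collapse = ", ")))
})

#' Indices of outliers found by the repeated Grubbs test
#' @param x A [GrubbsResult-class].
#' @return Integer indices into the input vector, in removal order.
#' @export
outlierIndices <- function(x) x@outlierIndices
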