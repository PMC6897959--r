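#' Simulate a Cas3-edited allele population
#'
#' Each allele is independently edited with probability
#' \code{editRate(cfg)}.  An edited allele carries one contiguous deletion:
#' the PAM-proximal breakpoint sits \code{offset} bp from the target edge on
#' the deletion side (offset ~ exponential, mean \code{startOffsetMean}) and
#' the deletion length is log-normal (calibrated by default so that 56.5%
#' of deletions are < 3 kb and 86.4% are < 10 kb).  With probability
#' \code{upstreamFraction} the deletion extends to the PAM-upstream side
#' (coordinates below the PAM start for \code{+} targets, above the PAM end
#' for \code{-}); otherwise it extends from the protospacer-distal edge
#' downstream.  Deletions are truncated at genome boundaries; the spacer
#' and PAM are retained in every allele, edited or not.
#'
#' @param genome Reference (`DNAStringSet` of length 1 or character).
#' @param target A [TargetSite-class].
#' @param cfg An [EditConfig-class].
#' @param nAlleles Number of alleles to draw (>= 1).
#' @return An [AlleleSet-class] with uniform weights.
#' @examples
#' g <- simulateGenome(50000, seed = 1)
#' pl <- plantProtospacer(g, strrep("ACGT", 8), "AAG", 40000, "+")
#' als <- simulateCas3Alleles(pl$genome, pl$target, editConfig(seed = 2), 10)
#' @export
simulateCas3Alleles <- function(genome, target, cfg, nAlleles) {
    ref <- .asReference(genome)
    stopifnot(is(target, "TargetSite"), is(cfg, "EditConfig"))
    nAlleles <- as.integer(nAlleles)
    if (nAlleles < 1L) stop("nAlleles must be >= 1")
    L <- nchar(ref[[1]])

    draw <- .withSeed(cfg@seed, {
        edited <- rbinom(nAlleles, 1L, cfg@editRate) == 1L
        offs <- round(rexp(nAlleles, rate = 1 / max(cfg@startOffsetMean, 1e-9)))
        sizes <- pmax(1, round(rlnorm(nAlleles, cfg@sizeMeanlog, cfg@sizeSdlog)))
        ups <- rbinom(nAlleles, 1L, cfg@upstreamFraction) == 1L
        list(edited = edited, offs = offs, sizes = sizes, ups = ups)
    })

    plus <- target@strand == "+"
    edits <- vector("list", nAlleles)
    for (i in seq_len(nAlleles)) {
        if (!draw$edited[i]) { edits[[i]] <- list(); next }
        off <- draw$offs[i]; sz <- draw$sizes[i]
        if (draw$ups[i]) {
            ## PAM-upstream side
            if (plus) {
                d2 <- target@pamStart - off
                d1 <- d2 - sz
            } else {
                d1 <- target@pamEnd + off
                d2 <- d1 + sz
            }
        } else {
            ## protospacer-distal (downstream) side
            if (plus) {
                d1 <- target@protoEnd + off
                d2 <- d1 + sz
            } else {
                d2 <- target@protoStart - off
                d1 <- d2 - sz
            }
        }
        d1 <- max(0L, as.integer(d1)); d2 <- min(L, as.integer(d2))
        if (d2 - d1 < 1L) { edits[[i]] <- list(); next }
        edits[[i]] <- list(list(type = "deletion", start = d1, end = d2))
    }
    alleleSet(ref[[1]], edits, parentName = names(ref))
}

#' Simulate a Cas9-edited allele population
#'
#' Cas9 cleaves 3 bp from the PAM-proximal end of a 20-nt protospacer
#' (between guide positions 17 and 18); edited alleles carry one small
#' insertion or deletion centred at that cut.  Indel sizes are drawn from a
#' truncated geometric over 1..\code{maxIndel} (small indels dominate, as
#' in amplicon data); insertions and deletions are equally likely.
#'
#' @param genome Reference (`DNAStringSet` of length 1 or character).
#' @param target A [TargetSite-class] with a 20-bp protospacer and 3' PAM.
#' @param indelRate Fraction of alleles edited.
#' @param maxIndel Largest indel size in bp (default 50).
#' @param geomProb Geometric decay of the size distribution (default 0.25).
#' @param nAlleles Number of alleles.
#' @param seed Integer seed.
#' @return An [AlleleSet-class] with uniform weights.
#' @export
simulateCas9Alleles <- function(genome, target, indelRate, nAlleles,
                                maxIndel = 50L, geomProb = 0.25,
                                seed = 1L) {
    ref <- .asReference(genome)
    stopifnot(is(target, "TargetSite"))
    if (target@protoEnd - target@protoStart != 20L)
        stop("Cas9 target must have a 20-bp protospacer")
    nAlleles <- as.integer(nAlleles)
    ## blunt cut 3 bp from the PAM-proximal protospacer end
    cut0 <- if (target@strand == "+") target@protoEnd - 3L
            else target@protoStart + 3L
    szProb <- geomProb * (1 - geomProb)^(seq_len(maxIndel) - 1L)
    draw <- .withSeed(seed, {
        edited <- rbinom(nAlleles, 1L, indelRate) == 1L
        sizes <- sample.int(maxIndel, nAlleles, replace = TRUE, prob = szProb)
        isIns <- rbinom(nAlleles, 1L, 0.5) == 1L
        insSeq <- vapply(sizes, function(k)
            paste(sample(c("A", "C", "G", "T"), k, TRUE), collapse = ""),
            character(1))
        list(edited = edited, sizes = sizes, isIns = isIns, insSeq = insSeq)
    })
    L <- nchar(ref[[1]])
    edits <- vector("list", nAlleles)
    for (i in seq_len(nAlleles)) {
        if (!draw$edited[i]) { edits[[i]] <- list(); next }
        sz <- draw$sizes[i]
        if (draw$isIns[i]) {
            edits[[i]] <- list(list(type = "insertion", start = cut0,
                                    end = cut0, seq = draw$insSeq[i]))
        } else {
            d1 <- max(0L, cut0 - sz %/% 2L)
            d2 <- min(L, d1 + sz)
            edits[[i]] <- list(list(type = "deletion", start = d1, end = d2))
        }
    }
    alleleSet(ref[[1]], edits, parentName = names(ref))
}

#' Construct an allele population containing an inversion
#'
#' Utility for testing inversion evidence: a fraction of alleles carries an
#' inversion of the given parent interval, the rest are unedited.
#'
#' @param genome Reference (`DNAStringSet` of length 1 or character).
#' @param start,end Inverted interval, 0-based half-open.
#' @param invFraction Fraction of alleles carrying the inversion.
#' @param nAlleles Number of alleles.
#' @return An [AlleleSet-class].
#' @export
simulateInversionAllele <- function(genome, start, end, invFraction = 0.5,
                                    nAlleles = 10L) {
    ref <- .asReference(genome)
    nInv <- round(invFraction * nAlleles)
    edits <- c(
        replicate(nInv, list(list(type = "inversion",
                                  start = as.integer(start),
                                  end = as.integer(end))), simplify = FALSE),
        replicate(nAlleles - nInv, list(), simplify = FALSE))
    alleleSet(ref[[1]], edits, parentName = names(ref))
}

#' Realise the sequence of one allele
#'
#' Applies an allele's edits to the parent sequence.
#'
#' @param x An [AlleleSet-class].
#' @param i Allele index.
#' @return Character sequence of the allele.
#' @export
alleleSequence <- function(x, i) {
    s <- x@parentSeq
    eds <- x@edits[[i]]
    if (!length(eds)) return(s)
    ## apply right-to-left so earlier coordinates stay valid
    ord <- order(vapply(eds, function(e) e$start, 0), decreasing = TRUE)
    for (e in eds[ord]) {
        if (e$type == "deletion") {
            s <- paste0(substr(s, 1L, e$start), substring(s, e$end + 1L))
        } else if (e$type == "insertion") {
            s <- paste0(substr(s, 1L, e$start), e$seq,
                        substring(s, e$start + 1L))
        } else if (e$type == "inversion") {
            s <- paste0(substr(s, 1L, e$start),
                        .revcomp(substr(s, e$start + 1L, e$end)),
                        substring(s, e$end + 1L))
        }
    }
    s
}

#' Planted deletion truth of an allele set
#'
#' Extracts each allele's deletion as one truth record; used to compare
#' breakpoint calls with the simulation ground truth and to feed
#' [summarizeDeletions()] with generator-level draws.
#'
#' @param x An [AlleleSet-class].
#' @param target A [TargetSite-class] used to orient offsets.
#' @return A deletion-call `data.frame` (see
#'   [callDeletionsNearTarget()]) with one row per deleted allele;
#'   `readId` holds the allele index.
#' @export
allelesToCalls <- function(x, target) {
    rows <- list()
    for (i in seq_along(x@edits)) {
        for (e in x@edits[[i]]) {
            if (e$type != "deletion") next
            rows[[length(rows) + 1L]] <-
                data.frame(chrom = x@parentName, start = e$start,
                           end = e$end, readId = sprintf("allele%06d", i),
                           stringsAsFactors = FALSE)
        }
    }
    if (!length(rows)) return(.annotateCalls(NULL, target))
    .annotateCalls(do.call(rbind, rows), target)
}
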