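#' Simulate a random reference sequence
#'
#' Draws an i.i.d. nucleotide sequence with the requested GC content.  Used
#' as the stand-in reference on which protospacers are planted and allele
#' populations are built.
#'
#' @param length Sequence length in bp (>= 1).
#' @param gc Target GC fraction in [0, 1].
#' @param seed Integer seed; identical arguments give byte-identical
#'   sequences.
#' @param name Sequence name (default `"chrS"`).
#' @return A named `DNAStringSet` of length 1.
#' @examples
#' g <- simulateGenome(1000, gc = 0.41, seed = 7)
#' @importFrom Biostrings DNAStringSet
#' @export
simulateGenome <- function(length, gc = 0.5, seed = 1L, name = "chrS") {
    length <- as.integer(length)
    if (is.na(length) || length < 1L)
        stop("length must be a positive integer")
    if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
    bases <- .withSeed(seed,
        sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)))
    out <- DNAStringSet(paste(bases, collapse = ""))
    names(out) <- name
    out
}

#' Plant a protospacer and PAM into a reference
#'
#' Overwrites the reference so that it contains the PAM followed by the
#' protospacer (the spacer sequence) at the stated position.  On the
#' \code{-} strand, the reverse complement of \code{pam + spacer} is written
#' on the forward sequence so that reading the minus strand 5' to 3' yields
#' PAM then protospacer.
#'
#' @param genome Named `DNAStringSet` (length 1) or character sequence.
#' @param spacer Spacer sequence, 5' to 3' (32 nt for type I-E).
#' @param pam 3-nt PAM.
#' @param position 0-based start of the protospacer on the forward strand.
#' @param strand `"+"` or `"-"`.
#' @param pamSide `"five_prime"` (type I-E, default) or `"three_prime"`
#'   (Cas9).
#' @return A list with elements `genome` (modified `DNAStringSet`) and
#'   `target` (a [TargetSite-class]).
#' @examples
#' g <- simulateGenome(10000, seed = 1)
#' pl <- plantProtospacer(g, strrep("ACGT", 8), "AAG", 5000, "+")
#' pl$target
#' @export
plantProtospacer <- function(genome, spacer, pam = "AAG", position,
                             strand = c("+", "-"),
                             pamSide = c("five_prime", "three_prime")) {
    strand <- match.arg(strand)
    pamSide <- match.arg(pamSide)
    ref <- .asReference(genome)
    if (length(ref) != 1L)
        stop("plantProtospacer expects a single-sequence reference")
    seqname <- names(ref)
    s <- ref[[1]]
    n <- nchar(s)
    spacer <- toupper(spacer); pam <- toupper(pam)
    if (!.validDna(spacer)) stop("spacer must be an ACGT string")
    if (!grepl("^[ACGT]{3}$", pam)) stop("pam must be a 3-nt ACGT string")
    L <- nchar(spacer)
    position <- as.integer(position)

    target <- targetSite(seqname, position, L, strand, pam, pamSide)
    lo <- min(target@protoStart, target@pamStart)
    hi <- max(target@protoEnd, target@pamEnd)
    if (lo < 0L || hi > n)
        stop("planted PAM+protospacer does not fit in the genome")

    ## assemble in spacer orientation, then place on the forward strand
    block5to3 <- if (pamSide == "five_prime") paste0(pam, spacer)
                 else paste0(spacer, pam)
    fwdBlock <- if (strand == "+") block5to3 else .revcomp(block5to3)
    substr(s, lo + 1L, hi) <- fwdBlock

    out <- DNAStringSet(s)
    names(out) <- seqname
    list(genome = out, target = target)
}
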