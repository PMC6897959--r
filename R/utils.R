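## Internal helpers shared across modules.

#' @importFrom withr with_seed
.withSeed <- function(seed, code) {
    if (is.null(seed) || is.na(seed)) return(force(code))
    withr::with_seed(as.integer(seed), code)
}

## reverse complement of plain character strings (vectorised)
.revcomp <- function(x) {
    comp <- chartr("ACGTN", "TGCAN", x)
    vapply(strsplit(comp, "", fixed = TRUE),
           function(ch) paste(rev(ch), collapse = ""), character(1))
}

## split a sequence into a character vector of single bases
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

## expand a PAM that may contain N into a positionwise matcher: returns a
## function(charsMatrixColumnList) -> logical.  Used by the POT scanner.
.pamMatches <- function(chars, start0, pam) {
    ## chars: character vector of the sequence; start0: 0-based starts of the
    ## 3-nt PAM window (may be out of range -> FALSE); pam: 3-nt ACGTN.
    n <- length(chars)
    ok <- start0 >= 0L & (start0 + 3L) <= n
    res <- ok
    p <- .chars(pam)
    for (k in 1:3) {
        idx <- start0 + k          # 1-based position of PAM base k
        base <- rep(NA_character_, length(start0))
        base[ok] <- chars[idx[ok]]
        mk <- if (p[k] == "N") base %in% c("A", "C", "G", "T")
              else !is.na(base) & base == p[k]
        res <- res & mk
    }
    res
}

## coerce a reference argument (character, DNAString, DNAStringSet, or a
## named character vector) to a named character vector of sequences
#' @importFrom Biostrings DNAString DNAStringSet
.asReference <- function(genome) {
    if (is(genome, "DNAStringSet")) {
        seqs <- as.character(genome)
        if (is.null(names(seqs)))
            names(seqs) <- paste0("seq", seq_along(seqs))
        return(seqs)
    }
    if (is(genome, "DNAString"))
        return(c(chrS = as.character(genome)))
    if (is.character(genome)) {
        if (is.null(names(genome)))
            names(genome) <- if (length(genome) == 1L) "chrS"
                             else paste0("seq", seq_along(genome))
        return(toupper(genome))
    }
    stop("unsupported reference type: ", class(genome)[1])
}

## stable 0-based half-open interval data.frame printer columns
.emptySiteFrame <- function() {
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), pamObserved = character(),
               stringsAsFactors = FALSE)
}
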