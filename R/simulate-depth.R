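#' Simulate an amplicon read-depth track
#'
#' Per-base depth over a region is Poisson with mean proportional to the
#' weighted fraction of alleles that retain each base: bases inside a
#' deletion on a fraction f of alleles have expected depth
#' `(1 - f) * nominalDepth`.  This emulates the coverage drop used by the
#' coverage-ratio efficiency estimator; PCR amplification bias is not
#' modelled.
#'
#' @param alleles An [AlleleSet-class].
#' @param start,end Region in parent coordinates, 0-based half-open.
#' @param nominalDepth Expected depth on fully retained bases
#'   (default 2000, a capture/amplicon-scale depth).
#' @param seed Integer seed; `NA` for a noise-free expected-depth track.
#' @return A `data.frame` with columns `chrom`, `pos` (0-based) and
#'   `depth`.
#' @examples
#' g <- simulateGenome(20000, seed = 1)
#' pl <- plantProtospacer(g, strrep("ACGT", 8), "AAG", 15000, "+")
#' als <- simulateCas3Alleles(pl$genome, pl$target, editConfig(seed = 2), 500)
#' d <- simulateAmpliconDepth(als, 10000, 16000, seed = 3)
#' @export
simulateAmpliconDepth <- function(alleles, start, end,
                                  nominalDepth = 2000, seed = 1L) {
    stopifnot(is(alleles, "AlleleSet"))
    start <- as.integer(start); end <- as.integer(end)
    L <- nchar(alleles@parentSeq)
    if (start < 0L || end > L || end <= start)
        stop("region must lie within the parent genome")
    pos <- start:(end - 1L)
    retained <- rep(0, length(pos))
    for (i in seq_along(alleles@edits)) {
        w <- alleles@weights[i]
        lost <- rep(FALSE, length(pos))
        for (e in alleles@edits[[i]]) {
            if (e$type == "deletion")
                lost <- lost | (pos >= e$start & pos < e$end)
        }
        retained <- retained + w * !lost
    }
    mu <- nominalDepth * retained
    depth <- if (is.null(seed) || is.na(seed)) mu
             else .withSeed(seed, rpois(length(mu), mu))
    data.frame(chrom = alleles@parentName, pos = pos, depth = depth,
               stringsAsFactors = FALSE)
}
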