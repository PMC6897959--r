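# Independent oracles, written naively on purpose: per-position string
# scanning for the POT search and an explicit-formula implementation of
# the repeated Grubbs test.  They never share code with the package
# internals.

.oRevcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = "")
}

.oPamHit <- function(obs, pamSet) {
    if (nchar(obs) != 3L) return(FALSE)
    oc <- strsplit(obs, "")[[1]]
    if (any(!oc %in% c("A", "C", "G", "T"))) return(FALSE)
    for (p in pamSet) {
        pc <- strsplit(p, "")[[1]]
        if (all(pc == "N" | pc == oc)) return(TRUE)
    }
    FALSE
}

# Brute-force POT scanner over every placement on both strands.
# Returns a data.frame with chrom, start0 (0-based protospacer start on
# the forward strand), strand, runLen (maximal PAM-proximal consecutive
# matches, wildcards auto-match) and mm (mismatches over non-wildcard
# positions).  pamSide: "five_prime" or "three_prime".
oraclePotScan <- function(ref, spacer, pamSet,
                          pamSide = "five_prime", wildcardPeriod = 6) {
    L <- nchar(spacer)
    sp <- strsplit(spacer, "")[[1]]
    isWild <- if (is.na(wildcardPeriod)) rep(FALSE, L)
              else (seq_len(L) %% wildcardPeriod) == 0
    rows <- list()
    for (chrom in names(ref)) {
        s <- ref[[chrom]]
        n <- nchar(s)
        for (start0 in 0:(n - L)) {
            for (strand in c("+", "-")) {
                proto <- substr(s, start0 + 1, start0 + L)
                if (strand == "-") proto <- .oRevcomp(proto)
                pamLeftFwd <- (strand == "+") == (pamSide == "five_prime")
                pamWin <- if (pamLeftFwd) {
                    if (start0 < 3) next
                    substr(s, start0 - 2, start0)
                } else {
                    if (start0 + L + 3 > n) next
                    substr(s, start0 + L + 1, start0 + L + 3)
                }
                pamObs <- if (strand == "+") pamWin else .oRevcomp(pamWin)
                if (!.oPamHit(pamObs, pamSet)) next
                pc <- strsplit(proto, "")[[1]]
                match <- ifelse(isWild, pc %in% c("A", "C", "G", "T"),
                                pc == sp)
                run <- 0L
                for (j in seq_len(L)) {
                    if (match[j]) run <- run + 1L else break
                }
                mm <- sum(!match[!isWild])
                rows[[length(rows) + 1L]] <- data.frame(
                    chrom = chrom, start0 = start0, strand = strand,
                    runLen = run, mm = mm, stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(rows))
        return(data.frame(chrom = character(), start0 = integer(),
                          strand = character(), runLen = integer(),
                          mm = integer(), stringsAsFactors = FALSE))
    do.call(rbind, rows)
}

# canonical site-set key for comparing package output with the oracle
siteKey <- function(chrom, start0, strand)
    sort(paste(chrom, start0, strand, sep = ":"))

grKey <- function(gr)
    siteKey(as.character(GenomicRanges::seqnames(gr)),
            GenomicRanges::start(gr) - 1L,
            as.character(GenomicRanges::strand(gr)))

# explicit repeated Grubbs oracle (one-sided max)
oracleGrubbs <- function(x, alpha = 0.05) {
    removed <- numeric()
    while (length(x) >= 3) {
        n <- length(x)
        G <- (max(x) - mean(x)) / sd(x)
        if (is.nan(G)) break
        t <- qt(1 - alpha / n, df = n - 2)
        crit <- (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
        if (G > crit) {
            removed <- c(removed, max(x))
            x <- x[-which.max(x)]
        } else break
    }
    removed
}
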