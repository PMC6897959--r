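#!/usr/bin/env bash
# Whole-genome PDD analysis of Cas3-edited vs control human WGS.
#
# Input: coordinate-sorted, indexed BAMs for the edited and control
# samples (e.g. realigned from DDBJ SRA accessions DRA008717/DRA008718;
# download and alignment are up to the user -- bwa mem to GRCh38,
# duplicate-marked).  Windows of 100 kb, count filter 20, repeated Grubbs
# at alpha 0.05 on log PDD.
#
# Usage: wgs_pdd.sh edited.bam control.bam /path/to/outdir
set -euo pipefail
EDITED=${1:?edited BAM required}
CONTROL=${2:?control BAM required}
OUT=${3:?output directory required}
mkdir -p "$OUT"

Rscript - "$EDITED" "$CONTROL" "$OUT" <<'EOF'
args <- commandArgs(trailingOnly = TRUE)
library(cas3edit)
library(Rsamtools)
sl <- scanBamHeader(args[1])[[1]]$targets
ep <- evidenceParams(windowSize = 100000L, minCount = 20L)
wE <- windowCounts(classifyEvidence(args[1], ep), ep$windowSize, sl)
wC <- windowCounts(classifyEvidence(args[2], ep), ep$windowSize, sl)
pdd <- callPddOutliers(computePdd(wE, wC, ep$minCount), alpha = 0.05)
df <- data.frame(chrom = as.character(GenomicRanges::seqnames(pdd)),
                 start = GenomicRanges::start(pdd) - 1L,
                 end = GenomicRanges::end(pdd),
                 as.data.frame(S4Vectors::mcols(pdd)))
write.table(df, file.path(args[3], "pdd_genomewide.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
df <- df[order(-df$PDD), ]
cat("top windows by PDD:\n")
print(head(df, 12))
EOF
# Expected behaviour on the published data: the on-target 100-kb window
# scores highest (PDD ~5.2 at the EMX1 locus, ~16% editing efficiency via
# the 5.24 -> 16.1% calibration); roughly ten other windows exceed
# PDD 3.5, driven by short-insert artifacts on SINE repeats rather than
# Cas3 activity.  Filter/sidedness policies are flags on computePdd() and
# callPddOutliers() if exact reproduction requires toggling them.
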