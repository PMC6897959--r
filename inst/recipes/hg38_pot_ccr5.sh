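#!/usr/bin/env bash
# Full-genome POT search for a CCR5 type I-E spacer on GRCh38.
# As hg38_pot_emx1.sh, but with the published CCR5 thresholds: consecutive
# mode minimum 16 nt; mismatch mode up to 7 mismatches.
#
# Usage: hg38_pot_ccr5.sh /path/to/hg38.fa /path/to/outdir SPACER32NT
set -euo pipefail
REF=${1:?reference FASTA required}
OUT=${2:?output directory required}
SPACER=${3:?32-nt spacer sequence required}
mkdir -p "$OUT"

Rscript - "$REF" "$OUT" "$SPACER" <<'EOF'
args <- commandArgs(trailingOnly = TRUE)
library(cas3edit)
library(Biostrings)
ref <- readDNAStringSet(args[1])
spacer <- args[3]
qc <- spacerQuery(spacer, mode = "consecutive", minConsecutive = 16L)
sc <- findPotConsecutive(ref, qc)
potReport(sc, qc, ref, tsv = file.path(args[2], "ccr5_consecutive.tsv"),
          bed = file.path(args[2], "ccr5_consecutive.bed"))
qm <- spacerQuery(spacer, mode = "mismatch", maxMismatches = 7L)
sm <- findPotMismatch(ref, qm)
potReport(sm, qm, ref, tsv = file.path(args[2], "ccr5_mismatch.tsv"),
          bed = file.path(args[2], "ccr5_mismatch.bed"))
cat("consecutive sites:", length(sc), "\nmismatch sites:", length(sm), "\n")
EOF
# Expected scale for the published CCR5 spacer: ~70 sites in consecutive
# mode (16-18 nt matches) and ~110 in mismatch mode, subject to the
# deduplication caveat noted in the EMX1 recipe.
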