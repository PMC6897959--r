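---
title: "Detecting and profiling CRISPR-Cas3 large deletions with cas3edit"
author: "cas3edit maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and profiling CRISPR-Cas3 large deletions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas3edit)
```

# The biology and the analysis problem

The type I-E CRISPR effector is a two-part machine: the Cascade
surveillance complex (Cas5, Cas6, Cas7, Cas8, Cas11) binds a 32-nt crRNA
spacer to its genomic protospacer next to a 3-nt PAM (AAG is the
strongest in human cells; TAG, AAC, GAG, AGG and ATG are also active),
and then recruits the Cas3 nuclease-helicase.  Unlike Cas9, which leaves
small indels at a blunt cut, Cas3 translocates and degrades DNA
processively, so editing manifests as heterogeneous deletions of hundreds
of bp to tens of kb, extending almost exclusively to the PAM-upstream
side of the target, while the spacer and PAM themselves are retained.

This produces three analysis problems that standard amplicon-indel tools
do not solve, and which this package implements:

1. **Off-target candidate enumeration** (`findPotConsecutive()`,
   `findPotMismatch()`, `findPotCas9()`): the Cas7 backbone thumb
   displaces every sixth spacer base, so those positions carry no
   specificity and must be treated as automatic matches when scanning a
   genome for potential off-target (POT) sites.
2. **Genome-wide deletion detection** (`classifyEvidence()`,
   `windowCounts()`, `computePdd()`, `callPddOutliers()`,
   `captureSubtractionScore()`): large deletions leave split reads and
   discordant pairs.  Per tiling window, the split score SS and
   discordant score DS are edited/control count ratios and their product
   is the potential DNA degradation (PDD) score; outlier windows are
   found by repeatedly applying Grubbs' test to log PDD.
3. **Target-proximal deletion profiling** (`callDeletionsNearTarget()`,
   `summarizeDeletions()`, `ampliconEfficiency()`, `pddToEfficiency()`,
   `inversionCheck()`): breakpoint-exact deletion calls near the target,
   their size/offset/directionality distributions, and editing-efficiency
   estimates from coverage drop or from a PDD calibration.

A synthetic-data generator (`simulateGenome()`, `plantProtospacer()`,
`simulateCas3Alleles()`, `simulateCas9Alleles()`, `simulateAlignments()`,
`simulateAmpliconDepth()`) emulates Cas3-edited sequencing samples so
that every stage is verifiable without external data.

# The generative model behind the simulator

Each allele of an edited population carries at most one event.  A Cas3
allele is edited with probability `editRate`; the edit is a single
contiguous deletion (single bulk deletions per molecule; multi-segment
degradation is out of scope):

* the PAM-proximal breakpoint sits `offset` bp from the target edge,
  with `offset ~ Exponential(mean = 217 bp)`.  The exponential family is
  a modelling choice matched to the observed mean; the observed 90th
  percentile (421 bp) is not exactly exponential
  (`qexp(0.9) * 217 = 500`), so the family is configurable and we do not
  assert against 421;
* the deletion length is log-normal with parameters solved in closed
  form (`calibrateLogNormalSizes()`) from two CDF anchors,
  P(size < 3 kb) = 0.565 and P(size < 10 kb) = 0.864, reproducing the
  reported size spectrum analytically to better than 1e-9;
* the deletion extends PAM-upstream with probability
  `upstreamFraction = 0.95` (capturing the rare downstream starts), and
  is truncated at genome edges;
* `editRate` defaults to 0.3, a typical on-target Cas3 large-deletion
  efficiency (reported locus range roughly 4-60%, mean ~27%).

Cas9 alleles, the contrast case, carry one small indel (1-50 bp,
geometric sizes) centred at the blunt cut 3 bp from the PAM-proximal end
of a 20-nt protospacer.

## Read simulation and its evidence contract

`simulateAlignments()` samples fragments (`insert ~ Normal(mean, sd)`,
default 450 +/- 50; reads default 2 x 150 bp at 90x, the WGS design the
analysis targets) from each allele and reports reads in parent
coordinates:

* a read crossing a deletion junction is emitted as a primary
  soft-clipped alignment plus a supplementary alignment with an SA tag,
  so the breakpoint is recoverable *exactly*.  Real aligners require a
  minimum anchor; the simulator emits the evidence for any split so that
  breakpoint-exactness is testable.  Deletions of at most 50 bp and all
  insertions are instead encoded aligner-style as CIGAR `D`/`I`
  operations (such reads are deliberately *not* split evidence, mirroring
  how small Cas9 indels look in practice);
* a pair is flagged not-properly-paired when its reference span exceeds
  `insertMean + 4*insertSd`; at the defaults this bound (650 bp) sits
  below the 1-kb discordance threshold used downstream, so every
  deletion-spanning pair is discordant under either rule;
* the error model is substitution-only.  Indel sequencing errors would
  confound the breakpoint-exactness contract and are deliberately
  omitted;
* optional background artifacts - random soft clips (`noiseSplitRate`,
  per read) and chimeric distant mates (`noiseDiscRate`, per pair) -
  emulate the repeat-driven background that makes the minimum-count
  filter necessary on real data.  Both default to **0**, so that at zero
  error every evidence record is attributable to a planted edit (the
  soundness invariant the tests assert).

What the simulator does **not** model: PCR amplification bias (a known
confounder of amplicon-based estimates), instrument error profiles,
multi-segment degradation, and alignment ambiguity in repeats.  Passing
tests therefore demonstrate correctness of the *method*, not robustness
to every artifact of real libraries.

# POT search rules and edge policies

Both search modes anchor on a PAM from the query's PAM set (default
`r paste(CAS3_PAM_SET, collapse = ", ")`; entries may contain `N`)
immediately 5' of the candidate protospacer in spacer orientation, on
either strand.  Consecutive mode reports the maximal run of perfect
matches from spacer position 1 (PAM-proximal); mismatch mode counts
mismatches over the 27 non-wildcard positions of a 32-nt spacer.
Policies that the underlying publication-grade web searches leave
implicit are fixed here explicitly:

* coordinates are 0-based half-open in all tables and BED output; a
  site's strand is the strand on which the spacer reads 5'->3'
  PAM-proximal-first;
* one site per (locus, strand): overlapping PAM-set members yield a
  single site with the observed genomic PAM recorded;
* reference ambiguity codes (e.g. `N` runs) never match anything -
  including wildcard positions and PAM bases.  In mismatch mode an
  ambiguous base therefore counts as a mismatch even at a wildcard
  position;
* `minConsecutive` has no library default: the useful threshold is
  locus-specific (the shipped reproduction recipes use 17 for the EMX1
  search and 16 for CCR5), so the caller must choose;
* Cas9 mode uses 3'-NGG by default (the SpCas9 standard; the source
  analyses never state their Cas9 search PAM) and is configurable.

Correctness is established against an independent per-position
brute-force scanner (property-based oracle equivalence over randomized
genomes, spacers and PAM sets) rather than against hand-picked examples.
Full-genome scans are a linear sweep; hg38-scale searches are shipped as
documented recipes (`reproduceRecipe()`) rather than tests.

# Windowed PDD scoring and the repeated Grubbs test

Evidence classification: a read is *split* iff it has a supplementary
alignment or a soft clip of at least 20 bp (counted once per read at the
clip position - never once per supplementary record, which would double
count); a pair is *discordant* iff it lost the proper-pair flag or its
template span exceeds 1 kb (counted once per pair at the leftmost mate).
The span threshold keeps the definition aligner-agnostic while matching
the > 1 kb deletion focus.

Windows tile each reference sequence (100 kb default; 1 kb and 10 kb for
capture panels).  Before scoring, a window is removed if **either**
sample's split or discordant count is below `minCount = 20`.  The filter
is stated in the method only as "< 20"; inspecting both samples is this
package's default because the filter's evident purpose is to prevent
ratios with small or zero denominators, and it guarantees division
safety without pseudocounts.  A `filterPolicy = "control"` flag inspects
only the control, for sensitivity to that reading.

For survivors, `SS = splitE/splitC`, `DS = discE/discC`,
`PDD = SS * DS` (an exact product, asserted to full precision), and
`logPDD = log(PDD)` with the natural log - provably immaterial, since
Grubbs' statistic is invariant under affine transforms of its input (a
property test asserts this on random vectors).

Outliers: Grubbs' test is applied repeatedly to log PDD - compute
`G = (max - mean)/sd`, compare against the closed-form critical value
from the t-distribution at `alpha/n`, remove and repeat until
non-significance or n < 3.  One-sided (maximum) testing is the default
because degradation can only inflate PDD; two-sided is available.  Zero
variance yields no outliers; fewer than 3 values is an error.

# Deletion profiling decisions

* Calls derive from split reads whose breakpoint falls within a 1-kb
  flank of the target; the deleted interval is the gap between a
  primary alignment and its SA-tagged mate segment; calls are
  deduplicated per read.
* Distribution summaries use **unique deleted intervals** by default
  (one molecule yields many reads); `perRead = TRUE` weights by
  supporting reads, since the original per-deletion statistics do not
  state which convention they used.
* Quantiles are linear-interpolation (type 7), stated so p90 figures are
  reproducible.
* The start offset of a call is measured from the target edge on the
  deletion's side (PAM boundary for upstream deletions,
  protospacer-distal edge for downstream ones), signed positive
  upstream; summaries use the magnitude.
* Coverage-ratio efficiency: the published wording places the edited
  probe "downstream of the AAG-PAM" while deletions accumulate
  *upstream* of the PAM; the wording conflicts superficially with the
  deletion direction, so this package defines the edited probe as lying
  on the deletion-accumulating side (300 bp by default) and the control
  probe on the opposite side (100 or 300 bp), both configurable.  Probe
  depth is smoothed over a 10-bp window.  The estimator measures
  P(deletion covers the probe), not the edit rate: with the default
  217-bp offset distribution, roughly a quarter of deletions start
  beyond a 300-bp probe, and a constructed test asserts this bias.
  Unbiased recovery holds when all deletions cover the probe.
* PDD-to-efficiency conversion is a one-point linear calibration
  (`k = 16.1/5.24` percent per PDD unit from the on-target anchor);
  applying it to PDD 3.5 gives 10.75%, matching the printed 10.7% at
  1-decimal precision.

# Problem sizes, study conditions and numerical choices

Analyses in the tests and the acceptance script run at desk scale,
chosen once as the package's study conditions:

* **Detection condition**: 200-kb reference, 10-kb windows, 2 x 100 bp
  reads at 60x with 600 +/- 60 bp inserts, 200 alleles with
  `editRate = 0.3` and 5-kb PAM-upstream deletions, and background
  artifact rates equivalent to an expected 40 split and 40 discordant
  background counts per window per sample.  These rates keep control
  windows safely above the count filter
  (P(Poisson(40) < 20) ~ 2e-4) while the expected target-window log PDD
  (~1.2, from +18 junction-crossing reads and +54 deletion-spanning
  pairs over the 40-count background) clears the n = 20 Grubbs critical
  value.  Negative controls use a 100-kb reference under the same
  condition.
* **Distribution recovery** runs at the generator level with 10,000
  alleles on a 1-Mb reference (the target sits 950 kb in, so size
  truncation at the genome edge is negligible).
* **Oracle equivalence** uses 100 random 4-kb genomes; the brute-force
  oracle is an intentionally naive per-position scanner, and this size
  keeps the property suite fast while covering both strands, all PAM
  subsets and both modes.
* **Amplicon recovery** uses short start offsets (mean 50 bp) with
  ~5-kb deletions so that deletions cover the edited probe - the regime
  in which the coverage ratio is an unbiased estimator of the edit
  rate.

Other numerical choices: genome simulation is i.i.d. with exact GC
control; all randomness flows through explicit integer seeds
(`withr::with_seed`, so the global RNG state is never disturbed); window
binning is pure integer arithmetic (`(pos - 1) %/% w`); SS/DS ratios are
exact doubles with no pseudocounts (the count filter guarantees nonzero
denominators); ties in Grubbs removal resolve to the first maximum,
which cannot affect the removed *set*.

# Known limitations

* The PDD pipeline detects windows, not breakpoints; it is not a
  general SV caller and performs no assembly or genotyping.
* Single-point PDD calibration assumes proportionality between PDD and
  efficiency across loci; treat converted efficiencies as rough
  estimates.
* The simulator's background noise is homogeneous, whereas real
  backgrounds concentrate in repeats; the min-count filter's real-world
  behaviour is therefore only partially exercised.
* Capture-mode subtraction scoring is a plain count difference with no
  filter, as in the source method; whether a filter should apply there
  is genuinely unstated, so the choice is exposed rather than hidden.

# A minimal worked run

```{r pipeline, eval = FALSE}
out <- file.path(tempdir(), "demo")
res <- runPipeline(defaultRunConfig(), out)
res$pdd[S4Vectors::mcols(res$pdd)$outlier]
res$summary$fracLt
res$efficiency$value
```

The README shows this run with its printed output; `scripts/acceptance.R`
recomputes all headline quantities from scratch with a caller-chosen
seed.
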