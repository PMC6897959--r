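Package: cas3edit
Title: Detection and Profiling of CRISPR-Cas3-Mediated Large Genomic Deletions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing genome editing by the type I-E CRISPR-Cas3
    system, which degrades DNA processively and leaves long, unidirectional
    deletions upstream of the protospacer adjacent motif (PAM). The package
    enumerates potential off-target (POT) sites for 32-nt crRNA spacers with
    periodic wildcard positions, detects large-deletion signal genome-wide
    from split-read and discordant-pair evidence using windowed potential
    DNA degradation (PDD) scores with repeated Grubbs outlier testing, calls
    and characterises target-proximal deletions (size, start offset and
    directionality distributions), and estimates editing efficiency from
    amplicon coverage ratios. A synthetic-data generator produces reference
    sequences, Cas3- and Cas9-edited allele populations, paired-end SAM
    alignments with exact structural-variant evidence, and depth tracks, so
    that every stage is verifiable without external sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
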