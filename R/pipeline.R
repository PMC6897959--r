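## End-to-end orchestration: simulate -> svdetect -> delprofile, plus a
## standalone POT search, with a round-trippable configuration and a run
## manifest for reproducibility.

.defaultConfigList <- function() {
    list(
        seed = 1L,
        genome = list(length = 200000L, gc = 0.41, name = "chrS"),
        target = list(position = 158000L, strand = "+", pam = "AAG",
                      spacer = paste0("GGTGTGGTTCCAGAACCGGAGGACAAAGTACA")),
        edit = list(editRate = 0.3, startOffsetMean = 217,
                    sizeMeanlog = 7.79558636023, sizeSdlog = 1.2879332583,
                    upstreamFraction = 0.95),
        reads = list(readLength = 100L, insertMean = 600, insertSd = 60,
                     depth = 60, errorRate = 0, noiseSplitRate = 0.00667,
                     noiseDiscRate = 0.01334),
        evidence = list(minClip = 20L, discordantDistance = 1000L,
                        windowSize = 10000L, minCount = 20L),
        grubbs = list(alpha = 0.05, side = "one_sided_max"),
        delprofile = list(flank = 1000L),
        potsearch = list(mode = "mismatch", maxMismatches = 7L,
                         minConsecutive = 16L, wildcardPeriod = 6L),
        amplicon = list(nominalDepth = 2000, editedOffset = 300L,
                        controlOffset = 300L, window = 8000L)
    )
}

#' Default pipeline configuration
#'
#' The demo configuration: a 200-kb reference, a planted 32-nt protospacer
#' with an AAG PAM, a 30%-edited Cas3 allele population, 2 x 100 bp reads
#' at 60x with background noise calibrated to roughly 40 split and 40
#' discordant artifact counts per 10-kb window, and default analysis
#' thresholds.
#'
#' @return A nested named list; see [runPipeline()].
#' @export
defaultRunConfig <- function() .defaultConfigList()

.mergeConfig <- function(base, user, path = "") {
    if (is.null(user)) return(base)
    extra <- setdiff(names(user), names(base))
    if (length(extra))
        stop("unknown config key(s): ",
             paste0(sub("^\\.", "", paste0(path, ".", extra)),
                    collapse = ", "))
    for (k in names(user)) {
        base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
            .mergeConfig(base[[k]], user[[k]], paste0(path, ".", k))
        else user[[k]]
    }
    base
}

#' Read / write a pipeline configuration
#'
#' Configurations are YAML; unknown keys are rejected and a written
#' configuration reads back identically.
#'
#' @param path YAML file path.
#' @param config For [writeRunConfig()], a configuration list.
#' @return [readRunConfig()]: the merged configuration list.
#' @importFrom yaml read_yaml write_yaml
#' @export
readRunConfig <- function(path) {
    .mergeConfig(.defaultConfigList(), yaml::read_yaml(path))
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(config, path, precision = 12L)
    invisible(path)
}

#' Run the full simulation-and-detection pipeline
#'
#' Stages, in dependency order: (1) simulate a reference, plant the
#' protospacer, draw a Cas3 allele population and an unedited control, and
#' emit paired-end SAM alignments plus an amplicon depth track; (2)
#' classify evidence, count it in windows, compute PDD scores and call
#' Grubbs outliers; (3) call target-proximal deletions, summarise them,
#' and estimate the amplicon coverage-ratio efficiency; (4) run the POT
#' search for the spacer against the simulated reference.  All outputs and
#' a manifest (configuration, seed, package version, output checksums) are
#' written under `outdir`; rerunning with an identical configuration
#' reproduces identical files.
#'
#' @param config Configuration list (see [defaultRunConfig()]) or a YAML
#'   path.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results:
#'   `target`, `pdd` (annotated `GRanges`), `calls`, `summary`,
#'   `efficiency`, `potSites`, `manifest`.
#' @importFrom jsonlite write_json
#' @importFrom tools md5sum
#' @importFrom Biostrings writeXStringSet
#' @importFrom utils packageVersion
#' @export
runPipeline <- function(config = defaultRunConfig(), outdir) {
    if (is.character(config)) config <- readRunConfig(config)
    else config <- .mergeConfig(.defaultConfigList(), config)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(config$seed)
    pth <- function(f) file.path(outdir, f)

    ## ---- stage 1: simulate ----------------------------------------------
    g <- simulateGenome(config$genome$length, config$genome$gc,
                        seed = seed, name = config$genome$name)
    pl <- plantProtospacer(g, config$target$spacer, config$target$pam,
                           config$target$position, config$target$strand)
    target <- pl$target
    ec <- editConfig(editRate = config$edit$editRate,
                     startOffsetMean = config$edit$startOffsetMean,
                     sizeMeanlog = config$edit$sizeMeanlog,
                     sizeSdlog = config$edit$sizeSdlog,
                     upstreamFraction = config$edit$upstreamFraction,
                     seed = seed + 1L)
    nAll <- 200L
    alsE <- simulateCas3Alleles(pl$genome, target, ec, nAll)
    alsC <- alleleSet(pl$genome[[1]], replicate(nAll, list(),
                      simplify = FALSE), parentName = config$genome$name)
    rcfg <- function(s) readSimConfig(
        readLength = config$reads$readLength,
        insertMean = config$reads$insertMean,
        insertSd = config$reads$insertSd, depth = config$reads$depth,
        errorRate = config$reads$errorRate,
        noiseSplitRate = config$reads$noiseSplitRate,
        noiseDiscRate = config$reads$noiseDiscRate, seed = s)
    alnE <- simulateAlignments(alsE, rcfg(seed + 2L), pth("edited.sam"))
    alnC <- simulateAlignments(alsC, rcfg(seed + 3L), pth("control.sam"))
    writeXStringSet(pl$genome, pth("reference.fa"))
    truthCalls <- allelesToCalls(alsE, target)
    write.table(truthCalls[c("chrom", "start", "end", "readId")],
        pth("truth_deletions.bed"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    ampLo <- max(0L, config$target$position - config$amplicon$window)
    ampHi <- min(config$genome$length,
                 config$target$position + config$amplicon$window)
    dep <- simulateAmpliconDepth(alsE, ampLo, ampHi,
        nominalDepth = config$amplicon$nominalDepth, seed = seed + 4L)
    write.table(dep, pth("depth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

    ## ---- stage 2: svdetect ----------------------------------------------
    ep <- evidenceParams(config$evidence$minClip,
                         config$evidence$discordantDistance,
                         config$evidence$windowSize,
                         config$evidence$minCount)
    sl <- setNames(config$genome$length, config$genome$name)
    evE <- classifyEvidence(alnE, ep)
    evC <- classifyEvidence(alnC, ep)
    wE <- windowCounts(evE, ep$windowSize, sl)
    wC <- windowCounts(evC, ep$windowSize, sl)
    pdd <- computePdd(wE, wC, ep$minCount)
    if (length(pdd) >= 3L) {
        pdd <- callPddOutliers(pdd, config$grubbs$alpha,
                               config$grubbs$side)
    } else {
        mcols(pdd)$outlier <- logical(length(pdd))
        mcols(pdd)$grubbsRank <- rep(NA_integer_, length(pdd))
    }
    pddDf <- data.frame(chrom = as.character(seqnames(pdd)),
        start = start(pdd) - 1L, end = end(pdd),
        as.data.frame(mcols(pdd)), stringsAsFactors = FALSE)
    write.table(pddDf, pth("pdd.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

    ## ---- stage 3: delprofile --------------------------------------------
    calls <- callDeletionsNearTarget(alnE, target,
                                     config$delprofile$flank)
    write.table(calls, pth("deletions.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    summ <- summarizeDeletions(calls)
    eff <- ampliconEfficiency(dep, target,
        config$amplicon$editedOffset, config$amplicon$controlOffset)

    ## ---- stage 4: potsearch ---------------------------------------------
    q <- if (config$potsearch$mode == "mismatch")
        spacerQuery(config$target$spacer, mode = "mismatch",
            wildcardPeriod = config$potsearch$wildcardPeriod,
            maxMismatches = config$potsearch$maxMismatches)
    else spacerQuery(config$target$spacer, mode = "consecutive",
            wildcardPeriod = config$potsearch$wildcardPeriod,
            minConsecutive = config$potsearch$minConsecutive)
    sites <- if (config$potsearch$mode == "mismatch")
        findPotMismatch(pl$genome, q) else findPotConsecutive(pl$genome, q)
    potReport(sites, q, pl$genome, tsv = pth("sites.tsv"),
              bed = pth("sites.bed"))

    jsonlite::write_json(
        list(summary = summ, efficiency = eff,
             target = list(chrom = target@seqname,
                 protospacer = c(target@protoStart, target@protoEnd),
                 strand = target@strand, pam = target@pam)),
        pth("summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

    outputs <- c("reference.fa", "edited.sam", "control.sam", "depth.tsv",
                 "truth_deletions.bed", "pdd.tsv", "deletions.tsv",
                 "sites.tsv", "sites.bed", "summary.json")
    manifest <- list(
        seed = seed,
        package = "cas3edit",
        version = as.character(packageVersion("cas3edit")),
        config = config,
        checksums = as.list(md5sum(vapply(outputs, pth, ""))))
    jsonlite::write_json(manifest, pth("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(target = target, pdd = pdd, calls = calls,
                   summary = summ, efficiency = eff, potSites = sites,
                   manifest = manifest))
}

#' Emit a documented reproduction-recipe script
#'
#' Writes a runnable, commented shell script for the long-running external
#' reproductions (full-genome POT searches for the EMX1 and CCR5 spacers
#' on GRCh38, and the whole-genome PDD analysis of the deposited
#' DRA008717/DRA008718 read sets).  The recipes require user-supplied
#' reference and read data and are never downloaded automatically.
#'
#' @param name One of `"wgs_pdd"`, `"hg38_pot_emx1"`, `"hg38_pot_ccr5"`.
#' @param outdir Directory to write the script into.
#' @return Path of the written script.
#' @export
reproduceRecipe <- function(name = c("wgs_pdd", "hg38_pot_emx1",
                                     "hg38_pot_ccr5"),
                            outdir = ".") {
    if (!is.character(name) || length(name) != 1L ||
        !name %in% c("wgs_pdd", "hg38_pot_emx1", "hg38_pot_ccr5"))
        stop("unknown recipe; available: wgs_pdd, hg38_pot_emx1, ",
             "hg38_pot_ccr5")
    src <- system.file("recipes", paste0(name, ".sh"),
                       package = "cas3edit", mustWork = TRUE)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    dest <- file.path(outdir, paste0(name, ".sh"))
    file.copy(src, dest, overwrite = TRUE)
    Sys.chmod(dest, "0755")
    dest
}
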