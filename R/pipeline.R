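PIPELINE_DEFAULTS <- list(
    windowBp = 20000L,     # study value
    stepBp = 2000L,        # study value
    nPerm = 1000L,         # study value
    level = 0.95,          # study value
    indexMin = 0.3,        # study value
    depthMin = 7L,         # study value
    depthRule = "either",  # package default
    minMarkers = 3L,       # package default
    fpkmMin = 1,           # study value
    lfcMin = 1,            # study value
    qMax = 0.05,           # study value
    nReps = 3L,            # study value (biological replicates per parent)
    dispersion = 0.05,     # package default
    nGenesPerChrom = 25L,  # package default
    seed = 1L)

PIPELINE_PROVENANCE <- c(
    windowBp = "study", stepBp = "study", nPerm = "study", level = "study",
    indexMin = "study", depthMin = "study", depthRule = "package",
    minMarkers = "package", fpkmMin = "study", lfcMin = "study",
    qMax = "study", nReps = "study", dispersion = "package",
    nGenesPerChrom = "package", seed = "package")

#' Pipeline configuration
#'
#' Validated named list of every tunable of the end-to-end pipeline.
#' Unknown keys are rejected; each default carries a provenance tag
#' (`attr(cfg, "provenance")`) marking whether it reproduces the original
#' study design or is a package default.
#'
#' @param ... overrides of the defaults (see `PIPELINE_DEFAULTS` in the
#'   source): `windowBp`, `stepBp`, `nPerm`, `level`, `indexMin`,
#'   `depthMin`, `depthRule`, `minMarkers`, `fpkmMin`, `lfcMin`, `qMax`,
#'   `nReps`, `dispersion`, `nGenesPerChrom`, `seed`.
#' @param sim a [SimConfig] describing the cross to simulate.
#' @return a list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(..., sim = SimConfig()) {
    over <- list(...)
    unknown <- setdiff(names(over), names(PIPELINE_DEFAULTS))
    if (length(unknown))
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(PIPELINE_DEFAULTS, over)
    if (cfg$stepBp > cfg$windowBp) stop("stepBp must not exceed windowBp")
    if (cfg$level <= 0 || cfg$level > 1) stop("level must lie in (0, 1]")
    cfg$sim <- sim
    attr(cfg, "provenance") <- PIPELINE_PROVENANCE
    class(cfg) <- "pipelineConfig"
    cfg
}

#' Read a pipeline configuration from a declarative JSON file
#'
#' Top-level keys are pipeline settings; an optional `sim` object holds
#' [SimConfig] fields. Unknown keys in either block are rejected.
#'
#' @param path JSON file.
#' @return a `pipelineConfig`.
#' @examples
#' cfg <- readPipelineConfig(system.file("extdata", "config-example.json",
#'                                       package = "bsaseq"))
#' cfg$windowBp
#' @export
readPipelineConfig <- function(path) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    simArgs <- raw$sim
    raw$sim <- NULL
    sim <- if (is.null(simArgs)) SimConfig() else {
        known <- names(formals(SimConfig))
        unknown <- setdiff(names(simArgs), known)
        if (length(unknown))
            stop("unknown sim key(s): ", paste(unknown, collapse = ", "))
        do.call(SimConfig, simArgs)
    }
    do.call(pipelineConfig, c(raw, list(sim = sim)))
}

#' Simulate a complete bulked-segregant + RNA-seq experiment
#'
#' Orchestrates the generators: F2 genotypes, phenotypes, extreme bulks,
#' pooled bulk sequencing, gene models with chromosome sequence, and an
#' RNA-seq count matrix in which genes overlapping the QTL neighbourhood
#' (and a sprinkling of background genes) are planted as differentially
#' expressed. The planted truth (QTL position, DE plan) is returned
#' alongside the data.
#'
#' @param config a `pipelineConfig`.
#' @param seed integer seed for the whole simulation (defaults to
#'   `config$seed`); a given seed is bit-reproducible.
#' @return list with `geno`, `heights`, `bulks`, `variants`, `models`,
#'   `genome`, `counts`, `truth`.
#' @export
runSimulation <- function(config = pipelineConfig(), seed = config$seed) {
    stopifnot(inherits(config, "pipelineConfig"))
    sim <- config$sim
    set.seed(seed)
    geno <- simulateF2Population(sim)
    heights <- simulatePhenotypes(geno, sim)
    bulks <- selectBulks(heights, k = sim@bulkSize)
    gm <- simulateGeneModels(sim, nGenesPerChrom = config$nGenesPerChrom)
    variants <- simulateBulkReads(geno, bulks, sim, genome = gm$genome)
    geneGr <- geneRanges(gm$models)
    geneIds <- mcols(geneGr)$geneId
    ## plant DE: genes within 300 kb of the QTL (the scale of a BSA
    ## confidence region here) are down-regulated in the dwarf samples; a
    ## few background genes elsewhere go either way
    nearQtl <- as.character(seqnames(geneGr)) == sim@qtlChrom &
        abs((start(geneGr) + end(geneGr)) / 2 - sim@qtlPosBp) <= 300000
    bg <- sample(which(!nearQtl), min(5L, sum(!nearQtl)))
    dePlan <- data.frame(
        geneId = c(geneIds[nearQtl], geneIds[bg]),
        log2fc = c(rep(-2, sum(nearQtl)),
                   sample(c(-2, 2), length(bg), replace = TRUE)))
    counts <- simulateRnaseqCounts(geneIds, dePlan, nReps = config$nReps,
                                   dispersion = config$dispersion,
                                   baseMeanRange = c(1.5, 3))
    list(geno = geno, heights = heights, bulks = bulks, variants = variants,
         models = gm$models, genome = gm$genome, counts = counts,
         truth = list(qtlChrom = sim@qtlChrom, qtlPosBp = sim@qtlPosBp,
                      plantedDegs = dePlan))
}

#' Run the full pipeline on simulated (or supplied) data
#'
#' Executes phenotype summary, marker selection, SNP-index computation and
#' filtering, sliding-window delta(SNP-index) with permutation thresholds,
#' candidate-region calling, codon-level variant-effect classification,
#' differential expression, and the BSA x RNA-seq intersection with region
#' refinement, returning the final report. Stage-by-stage record counts
#' are logged to stderr (`quiet = TRUE` silences them).
#'
#' @param config a `pipelineConfig`.
#' @param data optional precomputed input list as from [runSimulation()];
#'   simulated when `NULL`.
#' @param outdir optional directory; when given, the report (JSON + TSV),
#'   the window profile TSV and the candidate-region BED are written there.
#' @param quiet suppress progress messages.
#' @return a `bsaseqReport` (see [buildReport()]); the intermediate
#'   objects are attached as `attr(report, "state")`.
#' @export
runPipeline <- function(config = pipelineConfig(), data = NULL,
                        outdir = NULL, quiet = FALSE) {
    stopifnot(inherits(config, "pipelineConfig"))
    log <- function(...) if (!quiet) message("[bsaseq] ", ...)
    if (is.null(data)) {
        log("simulating experiment (seed ", config$seed, ")")
        data <- runSimulation(config)
    }
    pheno <- summarizePhenotypes(data$heights)
    log("phenotype: n=", pheno$n, " skew=", round(pheno$skewness, 3),
        " kurt=", round(pheno$kurtosis, 3))
    informative <- callParentInformativeMarkers(data$variants)
    log("markers: ", length(data$variants), " raw, ",
        length(informative), " parent-informative")
    track <- computeSnpIndex(informative)
    track <- filterMarkers(track, indexMin = config$indexMin,
                           depthMin = config$depthMin,
                           depthRule = config$depthRule)
    log("markers after index/depth filter: ", length(track))
    profile <- windowProfile(track, windowBp = config$windowBp,
                             stepBp = config$stepBp,
                             minMarkers = config$minMarkers)
    profile <- permutationThreshold(track, profile, nPerm = config$nPerm,
                                    level = config$level,
                                    bulkSize = config$sim@bulkSize)
    regions <- callCandidateRegions(profile, track)
    log("windows: ", length(profile), "; candidate regions: ",
        length(regions))
    effects <- classifyVariants(data$variants, data$models, data$genome)
    bsaGenes <- genesWithNonsynInRegions(effects, regions, data$variants)
    if (nrow(bsaGenes)) {
        geneGr <- geneRanges(data$models)
        gid <- mcols(geneGr)$geneId
        bsaGenes$regionId <- vapply(bsaGenes$geneId, function(g) {
            hit <- findOverlaps(geneGr[gid == g], regions,
                                ignore.strand = TRUE)
            if (length(hit)) S4Vectors::subjectHits(hit)[1] else NA_integer_
        }, integer(1))
    } else {
        bsaGenes$regionId <- integer(0)
    }
    log("region genes with protein-altering sites: ", nrow(bsaGenes))
    counts <- data$counts
    sf <- sizeFactors(counts)
    groups <- factor(sub("_[0-9]+$", "", colnames(counts)),
                     levels = c("tall", "dwarf"))
    res <- nbTest(counts, groups, sf)
    geneGr <- geneRanges(data$models)
    lens <- setNames(width(geneGr), mcols(geneGr)$geneId)
    fpkm <- computeFpkm(counts, lens[rownames(counts)])
    res <- callDegs(res, fpkm = fpkm, lfcMin = config$lfcMin,
                    qMax = config$qMax, fpkmMin = config$fpkmMin)
    degs <- res[res$deg, , drop = FALSE]
    log("DEGs: ", nrow(degs), " (", sum(degs$direction == "down"), " down, ",
        sum(degs$direction == "up"), " up)")
    candidates <- intersectCandidates(bsaGenes, degs)
    refined <- refineRegions(regions, bsaGenes, res)
    report <- buildReport(pheno, refined, candidates,
                          config = pipelineConfigAsList(config),
                          truth = data$truth, seed = config$seed)
    log("retained regions: ", nrow(report$regions),
        "; candidate genes: ", nrow(report$candidateGenes),
        if (!is.null(report$truth))
            paste0("; true QTL recovered: ", report$truth$trueQtlRecovered)
        else "")
    attr(report, "state") <- list(track = track, profile = profile,
                                  regions = regions, refined = refined,
                                  effects = effects, bsaGenes = bsaGenes,
                                  deResults = res, fpkm = fpkm, sf = sf)
    if (!is.null(outdir)) {
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        writeReport(report, outdir)
        writeWindowProfileTsv(profile, file.path(outdir, "windows.tsv"))
        writeRegionsBed(refined, file.path(outdir, "regions.bed"))
    }
    report
}

pipelineConfigAsList <- function(config) {
    out <- unclass(config)
    sim <- out$sim
    out$sim <- list(
        nChromosomes = sim@nChromosomes, chromLengthBp = sim@chromLengthBp,
        nMarkersPerChrom = sim@nMarkersPerChrom, recombRate = sim@recombRate,
        qtlChrom = sim@qtlChrom, qtlPosBp = sim@qtlPosBp,
        qtlEffect = sim@qtlEffect, qtlDominance = sim@qtlDominance,
        baseline = sim@baseline, envSd = sim@envSd, popSize = sim@popSize,
        bulkSize = sim@bulkSize, parentDepthMean = sim@parentDepthMean,
        bulkDepthMean = sim@bulkDepthMean, seqError = sim@seqError)
    attr(out, "provenance") <- NULL
    out
}

#' Write a window profile as TSV
#' @param profile a [WindowProfile].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeWindowProfileTsv <- function(profile, path) {
    df <- data.frame(chrom = as.character(seqnames(profile)),
                     start = start(profile), end = end(profile),
                     as.data.frame(mcols(profile)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
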