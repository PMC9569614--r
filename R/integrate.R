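#' Intersect BSA candidate genes with differentially expressed genes
#'
#' Exact set intersection by gene id, joining the mutation evidence
#' (protein-altering site counts, region) with the expression evidence
#' (fold change, q, direction). An empty intersection that would become
#' non-empty after case-folding the ids is treated as an id-format mismatch
#' and raised as an error with a diagnostic, since it almost always means
#' the two inputs came from different annotation releases.
#'
#' @param bsaGenes `data.frame` with at least `geneId` and `nSites`
#'   (e.g. from [genesWithNonsynInRegions()]), optionally `regionId`.
#' @param degs `data.frame` of called DEGs (rows of a [callDegs()] result
#'   with `deg == TRUE`), keyed by `geneId`.
#' @return `data.frame` of candidate genes with columns from both sides,
#'   sorted by decreasing `nSites`.
#' @export
intersectCandidates <- function(bsaGenes, degs) {
    stopifnot("geneId" %in% colnames(bsaGenes), "geneId" %in% colnames(degs))
    common <- intersect(bsaGenes$geneId, degs$geneId)
    if (!length(common) && nrow(bsaGenes) && nrow(degs)) {
        foldedHits <- intersect(tolower(bsaGenes$geneId), tolower(degs$geneId))
        if (length(foldedHits))
            stop("gene id format mismatch between BSA and DE inputs ",
                 "(ids match after case-folding, e.g. '",
                 foldedHits[1], "'); harmonise the annotations")
    }
    keepDeg <- degs[match(common, degs$geneId),
                    intersect(c("geneId", "log2FoldChange", "q", "direction",
                                "expressed"), colnames(degs)),
                    drop = FALSE]
    out <- merge(bsaGenes[bsaGenes$geneId %in% common, , drop = FALSE],
                 keepDeg, by = "geneId")
    out[order(-out$nSites, out$geneId), , drop = FALSE]
}

#' Drop candidate regions without expression support
#'
#' A region is retained only if at least one of its mutated genes is both
#' expressed and differentially expressed; a region whose mutated genes are
#' all unexpressed or non-differential -- or which has no mutated gene at
#' all -- is excluded, mirroring the logic of discarding a
#' mapping-supported interval that transcription cannot corroborate.
#' Regions are never added.
#'
#' @param regions `GRanges` of candidate regions.
#' @param bsaGenes `data.frame` from [genesWithNonsynInRegions()] with an
#'   added `regionId` column (integer index into `regions`).
#' @param deResults [callDegs()] output with `deg` and (if available)
#'   `expressed` flags.
#' @return the retained subset of `regions`, with `candidateGeneIds`
#'   attached as a `CharacterList` metadata column.
#' @export
refineRegions <- function(regions, bsaGenes, deResults) {
    if (!length(regions)) return(regions)
    stopifnot("regionId" %in% colnames(bsaGenes))
    supported <- deResults$deg
    if (!is.null(deResults$expressed))
        supported <- supported & !is.na(deResults$expressed) & deResults$expressed
    supportedIds <- deResults$geneId[supported]
    keep <- logical(length(regions))
    lists <- vector("list", length(regions))
    for (i in seq_along(regions)) {
        genesHere <- bsaGenes$geneId[bsaGenes$regionId == i]
        good <- intersect(genesHere, supportedIds)
        keep[i] <- length(good) > 0
        lists[[i]] <- good
    }
    out <- regions[keep]
    mcols(out)$candidateGeneIds <- IRanges::CharacterList(lists[keep])
    out
}

#' Assemble the final machine- and human-readable report
#'
#' Bundles the phenotype summary, candidate-region table, per-gene evidence
#' and (when simulation truth is available) a truth comparison into one
#' list that serialises losslessly to JSON.
#'
#' @param phenotypeSummary one-row `data.frame` from
#'   [summarizePhenotypes()].
#' @param regions `GRanges` of retained candidate regions.
#' @param candidateGenes `data.frame` from [intersectCandidates()].
#' @param config named list of the pipeline parameters used.
#' @param truth optional list with `qtlChrom`/`qtlPosBp` and `plantedDegs`.
#' @param seed the seed the run used.
#' @return a list of class `bsaseqReport`.
#' @export
buildReport <- function(phenotypeSummary, regions, candidateGenes,
                        config = list(), truth = NULL, seed = NA_integer_) {
    regionDf <- if (length(regions))
        data.frame(chrom = as.character(seqnames(regions)),
                   start = start(regions), end = end(regions),
                   nSignificantWindows = mcols(regions)$nSignificantWindows,
                   peakDelta = mcols(regions)$peakDelta)
    else
        data.frame(chrom = character(), start = integer(), end = integer(),
                   nSignificantWindows = integer(), peakDelta = numeric())
    report <- list(
        phenotype = as.list(phenotypeSummary),
        regions = regionDf,
        candidateGenes = candidateGenes,
        config = config,
        seed = seed,
        configHash = rlang::hash(config))
    if (!is.null(truth)) {
        covered <- FALSE
        if (length(regions))
            covered <- any(as.character(seqnames(regions)) == truth$qtlChrom &
                           start(regions) <= truth$qtlPosBp &
                           end(regions) >= truth$qtlPosBp)
        report$truth <- list(
            qtlChrom = truth$qtlChrom, qtlPosBp = truth$qtlPosBp,
            trueQtlRecovered = covered,
            plantedDegs = truth$plantedDegs)
    }
    class(report) <- "bsaseqReport"
    report
}

#' Write / read a pipeline report
#'
#' The JSON file is the canonical machine-readable form and round-trips
#' through [readReport()]; TSV companions are written for the region and
#' candidate-gene tables.
#'
#' @param report a `bsaseqReport`.
#' @param dir output directory (created if needed).
#' @return invisibly, the path of the JSON file.
#' @export
writeReport <- function(report, dir) {
    stopifnot(inherits(report, "bsaseqReport"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(dir, "report.json")
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    utils::write.table(report$regions, file.path(dir, "regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$candidateGenes,
                       file.path(dir, "candidate_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeReport
#' @param path path to a `report.json`.
#' @export
readReport <- function(path) {
    report <- jsonlite::read_json(path, simplifyVector = TRUE)
    class(report) <- "bsaseqReport"
    report
}

#' @export
print.bsaseqReport <- function(x, ...) {
    cat("bsaseq pipeline report (seed ", x$seed, ")\n", sep = "")
    cat("  phenotype: n =", x$phenotype$n,
        sprintf("mean %.1f, sd %.1f, skewness %.3f, kurtosis %.3f\n",
                x$phenotype$mean, x$phenotype$sd,
                x$phenotype$skewness, x$phenotype$kurtosis))
    cat("  candidate regions:", nrow(x$regions), "\n")
    cat("  candidate genes:", nrow(x$candidateGenes), "\n")
    if (!is.null(x$truth))
        cat("  true QTL recovered:", x$truth$trueQtlRecovered, "\n")
    invisible(x)
}
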