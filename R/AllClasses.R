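#' @import methods
#' @importFrom S4Vectors metadata metadata<- mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width strand reduce
#'   findOverlaps countOverlaps
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
NULL

GT_LEVELS <- c("0/0", "1/1", "0/1", "./.")

#' Configuration of a simulated F2 bulked-segregant experiment
#'
#' Holds every tunable of the synthetic F2 cross: genome layout, marker map,
#' recombination rate, the quantitative trait locus (QTL) and its additive
#' effect, the phenotype noise, population and bulk sizes, and sequencing
#' depths. Defaults describe a desk-scale cross of 200 plants genotyped at
#' 2,000 markers on each of two 2-Mb chromosomes, with parents at ~10x and
#' 30-plant bulks at ~50x depth.
#'
#' @slot nChromosomes number of simulated chromosomes.
#' @slot chromLengthBp length of every chromosome, in bp.
#' @slot nMarkersPerChrom number of biallelic markers per chromosome.
#' @slot recombRate recombination rate in cM per Mb. The default (50) makes
#'   each desk-scale 2-Mb chromosome carry ~100 cM, the genetic length of a
#'   real crop chromosome, so linkage decay, window correlation and mapping
#'   resolution behave as in a genome-scale experiment.
#' @slot qtlChrom,qtlPosBp position of the single major QTL.
#' @slot qtlEffect additive phenotype shift (cm) per copy of the dwarf-parent
#'   allele; negative values make the dwarf-parent allele reduce height.
#' @slot qtlDominance dominance deviation (cm) of the heterozygote; 0 by
#'   default (strictly additive locus).
#' @slot baseline phenotype (cm) of an individual with zero dwarf alleles
#'   and zero environmental deviation.
#' @slot envSd standard deviation (cm) of the Normal environmental noise.
#' @slot popSize number of F2 individuals.
#' @slot bulkSize number of individuals in each extreme bulk.
#' @slot parentDepthMean,bulkDepthMean Poisson mean sequencing depth of the
#'   parent samples and of each bulk.
#' @slot seqError probability that a read reports the wrong allele
#'   (symmetric flip), must lie in [0, 0.5).
#' @slot seed integer seed used by [runSimulation()]; `NA` leaves the RNG
#'   state untouched.
#'
#' @seealso [SimConfig()] for the user constructor.
#' @export
setClass("SimConfig", representation(
    nChromosomes = "integer",
    chromLengthBp = "integer",
    nMarkersPerChrom = "integer",
    recombRate = "numeric",
    qtlChrom = "character",
    qtlPosBp = "integer",
    qtlEffect = "numeric",
    qtlDominance = "numeric",
    baseline = "numeric",
    envSd = "numeric",
    popSize = "integer",
    bulkSize = "integer",
    parentDepthMean = "numeric",
    bulkDepthMean = "numeric",
    seqError = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    cnt <- c(nChromosomes = object@nChromosomes,
             chromLengthBp = object@chromLengthBp,
             nMarkersPerChrom = object@nMarkersPerChrom,
             popSize = object@popSize,
             bulkSize = object@bulkSize)
    if (any(is.na(cnt)) || any(cnt < 0L))
        msg <- c(msg, "all counts must be >= 0")
    if (any(c(object@parentDepthMean, object@bulkDepthMean) < 0))
        msg <- c(msg, "sequencing depth means must be >= 0")
    if (is.na(object@seqError) || object@seqError < 0 || object@seqError >= 0.5)
        msg <- c(msg, "seqError must lie in [0, 0.5)")
    if (object@envSd < 0)
        msg <- c(msg, "envSd must be >= 0")
    if (length(msg) == 0 && object@nChromosomes > 0L) {
        chroms <- paste0("chr", seq_len(object@nChromosomes))
        if (!(object@qtlChrom %in% chroms))
            msg <- c(msg, "qtlChrom is not a simulated chromosome")
        else if (object@qtlPosBp < 1L || object@qtlPosBp > object@chromLengthBp)
            msg <- c(msg, "qtlPosBp outside the simulated chromosome")
    }
    if (length(msg) == 0 && 2L * object@bulkSize > object@popSize)
        msg <- c(msg, "2 * bulkSize must not exceed popSize")
    if (length(msg)) msg else TRUE
})

#' @param nChromosomes,chromLengthBp,nMarkersPerChrom,recombRate,qtlChrom,qtlPosBp,qtlEffect,qtlDominance,baseline,envSd,popSize,bulkSize,parentDepthMean,bulkDepthMean,seqError,seed
#'   see the corresponding slots.
#' @return `SimConfig()` returns a validated `SimConfig` object.
#' @examples
#' cfg <- SimConfig(seed = 1L)
#' cfg
#' @rdname SimConfig-class
#' @export
SimConfig <- function(nChromosomes = 2L, chromLengthBp = 2000000L,
                      nMarkersPerChrom = 2000L, recombRate = 50,
                      qtlChrom = "chr1", qtlPosBp = 1200000L,
                      qtlEffect = -15, qtlDominance = 0, baseline = 130,
                      envSd = 8, popSize = 200L, bulkSize = 30L,
                      parentDepthMean = 10, bulkDepthMean = 50,
                      seqError = 0.01, seed = NA_integer_) {
    new("SimConfig",
        nChromosomes = as.integer(nChromosomes),
        chromLengthBp = as.integer(chromLengthBp),
        nMarkersPerChrom = as.integer(nMarkersPerChrom),
        recombRate = as.numeric(recombRate),
        qtlChrom = as.character(qtlChrom),
        qtlPosBp = as.integer(qtlPosBp),
        qtlEffect = as.numeric(qtlEffect),
        qtlDominance = as.numeric(qtlDominance),
        baseline = as.numeric(baseline),
        envSd = as.numeric(envSd),
        popSize = as.integer(popSize),
        bulkSize = as.integer(bulkSize),
        parentDepthMean = as.numeric(parentDepthMean),
        bulkDepthMean = as.numeric(bulkDepthMean),
        seqError = as.numeric(seqError),
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:",
        object@nChromosomes, "chromosome(s) x",
        object@chromLengthBp, "bp,",
        object@nMarkersPerChrom, "markers/chrom\n")
    cat("  QTL at", object@qtlChrom, ":", object@qtlPosBp,
        " effect", object@qtlEffect, "cm/allele, envSd",
        object@envSd, "cm\n")
    cat("  F2 n =", object@popSize, ", bulks 2 x", object@bulkSize,
        ", depth parents ~", object@parentDepthMean,
        "x / bulks ~", object@bulkDepthMean, "x\n")
})

#' Genotype dosages of a simulated F2 population
#'
#' Stores the dosage of the dwarf-parent allele (0, 1 or 2 copies) for every
#' individual at every marker, together with the marker map as a
#' [GenomicRanges::GRanges]. Markers must be position-sorted within each
#' chromosome (equal positions are allowed and behave as fully linked).
#'
#' @slot dosage integer matrix, individuals x markers, values in {0, 1, 2}.
#' @slot markers `GRanges` of marker positions (width-1 ranges), one per
#'   dosage column.
#' @export
setClass("F2Genotypes", representation(
    dosage = "matrix",
    markers = "GRanges"
))

setValidity("F2Genotypes", function(object) {
    msg <- character()
    if (ncol(object@dosage) != length(object@markers))
        msg <- c(msg, "ncol(dosage) must equal length(markers)")
    d <- object@dosage
    if (length(d) && (!all(d %in% c(0L, 1L, 2L))))
        msg <- c(msg, "dosages must be 0, 1 or 2")
    pos <- split(start(object@markers), as.character(seqnames(object@markers)))
    if (any(vapply(pos, function(p) is.unsorted(p), logical(1))))
        msg <- c(msg, "marker positions must be non-decreasing within a chromosome")
    if (length(msg)) msg else TRUE
})

#' @rdname F2Genotypes-class
#' @param object,x an `F2Genotypes` object.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname F2Genotypes-class
#' @export
setMethod("dosages", "F2Genotypes", function(x) x@dosage)

#' @rdname F2Genotypes-class
#' @export
setGeneric("markerRanges", function(x) standardGeneric("markerRanges"))
#' @rdname F2Genotypes-class
#' @export
setMethod("markerRanges", "F2Genotypes", function(x) x@markers)

setMethod("show", "F2Genotypes", function(object) {
    cat("F2Genotypes:", nrow(object@dosage), "individuals x",
        length(object@markers), "markers on",
        length(unique(as.character(seqnames(object@markers)))),
        "chromosome(s)\n")
})

#' Per-marker SNP-index track
#'
#' A `GRanges`-derived container with one range per parent-informative
#' marker and the per-bulk SNP-index bookkeeping in its metadata columns:
#' `dwarfAllele` (which of ref/alt is carried by the dwarf parent),
#' `dwarfHigh`/`dwarfLow` (reads carrying that allele in each bulk),
#' `depthHigh`/`depthLow`, `indexHigh`/`indexLow` (the SNP-index, i.e. the
#' dwarf-parent allele read fraction, `NA` at zero depth) and `delta`
#' (`indexHigh - indexLow`, `NA` when either index is missing).
#'
#' The orientation convention (index = frequency of the dwarf-parent
#' allele, with the tall parent as reference) is recorded in
#' `metadata(x)$orientation` and can be flipped by recomputing with
#' `orientTo = "P1"`.
#'
#' @export
setClass("SnpIndexTrack", contains = "GRanges")

setValidity("SnpIndexTrack", function(object) {
    need <- c("dwarfAllele", "dwarfHigh", "dwarfLow",
              "depthHigh", "depthLow", "indexHigh", "indexLow", "delta")
    miss <- setdiff(need, colnames(mcols(object)))
    if (length(miss))
        return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
    ih <- mcols(object)$indexHigh
    il <- mcols(object)$indexLow
    ok <- function(v) all(is.na(v) | (v >= 0 & v <= 1))
    if (!ok(ih) || !ok(il))
        return("SNP-index values must lie in [0, 1] or be NA")
    if (any(mcols(object)$depthHigh < 0, na.rm = TRUE) ||
        any(mcols(object)$depthLow < 0, na.rm = TRUE))
        return("depths must be >= 0")
    TRUE
})

#' @rdname SnpIndexTrack-class
#' @param x a `SnpIndexTrack`.
#' @export
setGeneric("snpIndexHigh", function(x) standardGeneric("snpIndexHigh"))
#' @rdname SnpIndexTrack-class
#' @export
setMethod("snpIndexHigh", "SnpIndexTrack", function(x) mcols(x)$indexHigh)
#' @rdname SnpIndexTrack-class
#' @export
setGeneric("snpIndexLow", function(x) standardGeneric("snpIndexLow"))
#' @rdname SnpIndexTrack-class
#' @export
setMethod("snpIndexLow", "SnpIndexTrack", function(x) mcols(x)$indexLow)
#' @rdname SnpIndexTrack-class
#' @export
setGeneric("snpDelta", function(x) standardGeneric("snpDelta"))
#' @rdname SnpIndexTrack-class
#' @export
setMethod("snpDelta", "SnpIndexTrack", function(x) mcols(x)$delta)

setMethod("show", "SnpIndexTrack", function(object) {
    cat("SnpIndexTrack with", length(object), "markers;",
        "orientation:", metadata(object)$orientation %||% "unset", "\n")
    callNextMethod()
})

#' Sliding-window delta(SNP-index) profile
#'
#' A `GRanges`-derived container of fixed-width sliding windows with the
#' per-window marker count, mean per-bulk SNP-index, mean delta(SNP-index)
#' and (after [permutationThreshold()]) the lower/upper permutation
#' thresholds. Windows with fewer than `minMarkers` markers are masked
#' (`NA` means). Window size, step, masking threshold and the permutation
#' settings live in `metadata(x)`.
#'
#' @export
setClass("WindowProfile", contains = "GRanges")

setValidity("WindowProfile", function(object) {
    need <- c("nMarkers", "meanIndexHigh", "meanIndexLow", "meanDelta",
              "thresholdLo", "thresholdHi")
    miss <- setdiff(need, colnames(mcols(object)))
    if (length(miss))
        return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
    w <- metadata(object)$windowBp
    if (!is.null(w) && length(object) && !all(width(object) == w))
        return("all windows must have width windowBp")
    TRUE
})

#' @rdname WindowProfile-class
#' @param x a `WindowProfile`.
#' @export
setGeneric("windowDelta", function(x) standardGeneric("windowDelta"))
#' @rdname WindowProfile-class
#' @export
setMethod("windowDelta", "WindowProfile", function(x) mcols(x)$meanDelta)

#' @rdname WindowProfile-class
#' @export
setGeneric("windowThresholds", function(x) standardGeneric("windowThresholds"))
#' @rdname WindowProfile-class
#' @export
setMethod("windowThresholds", "WindowProfile", function(x)
    DataFrame(thresholdLo = mcols(x)$thresholdLo,
              thresholdHi = mcols(x)$thresholdHi))

setMethod("show", "WindowProfile", function(object) {
    md <- metadata(object)
    cat("WindowProfile:", length(object), "windows (",
        md$windowBp %||% NA, "bp /", md$stepBp %||% NA, "bp step );",
        sum(!is.na(mcols(object)$meanDelta)), "unmasked\n")
    callNextMethod()
})

#' Gene models with cached coding sequence layout
#'
#' Gene spans plus the coding-segment layout used by the codon-level effect
#' classifier. CDS segments are stored 5' to 3' (decreasing coordinates on
#' the minus strand); total CDS length must be divisible by 3 and segments
#' of one gene must not overlap.
#'
#' @slot genes `GRanges` of gene spans with a `geneId` metadata column;
#'   strand is meaningful.
#' @slot cds `GRangesList` of CDS segments, one element per gene, named by
#'   `geneId`, ordered 5' to 3'.
#' @export
setClass("GeneModels", representation(
    genes = "GRanges",
    cds = "GRangesList"
))

setValidity("GeneModels", function(object) {
    msg <- character()
    if (is.null(mcols(object@genes)$geneId))
        msg <- c(msg, "genes must carry a geneId metadata column")
    else if (!setequal(mcols(object@genes)$geneId, names(object@cds)))
        msg <- c(msg, "cds names must match gene ids")
    w <- sum(width(object@cds))
    if (length(w) && any(w %% 3L != 0L))
        msg <- c(msg, paste("CDS length not divisible by 3 for gene(s):",
                            paste(names(object@cds)[w %% 3L != 0L], collapse = ", ")))
    ov <- vapply(object@cds, function(gr)
        length(reduce(gr, min.gapwidth = 0L)) < length(gr), logical(1))
    if (any(ov))
        msg <- c(msg, "CDS segments of one gene must not overlap")
    if (length(msg)) msg else TRUE
})

#' @rdname GeneModels-class
#' @param x a `GeneModels` object.
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @rdname GeneModels-class
#' @export
setMethod("geneRanges", "GeneModels", function(x) x@genes)
#' @rdname GeneModels-class
#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))
#' @rdname GeneModels-class
#' @export
setMethod("cdsRanges", "GeneModels", function(x) x@cds)

setMethod("show", "GeneModels", function(object) {
    cat("GeneModels:", length(object@genes), "genes on",
        length(unique(as.character(seqnames(object@genes)))),
        "chromosome(s), mean CDS",
        if (length(object@cds)) round(mean(sum(width(object@cds)))) else 0,
        "bp\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
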