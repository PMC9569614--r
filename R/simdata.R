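#' @importFrom stats rbinom rpois rnorm rnbinom runif quantile rhyper
#'   setNames var sd cor
#' @importFrom GenomicRanges GRangesList
NULL

chromNames <- function(cfg) paste0("chr", seq_len(cfg@nChromosomes))

#' Draw a random marker map for a simulated genome
#'
#' Marker positions are sampled uniformly without replacement on each
#' chromosome and sorted, giving a strictly increasing map.
#'
#' @param cfg a [SimConfig].
#' @return `GRanges` of width-1 marker positions with seqlengths set.
#' @export
simulateMarkerMap <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    chroms <- chromNames(cfg)
    pos <- lapply(chroms, function(ch)
        sort(sample.int(cfg@chromLengthBp, cfg@nMarkersPerChrom)))
    gr <- GRanges(rep(chroms, lengths(pos)),
                  IRanges(unlist(pos), width = 1L))
    seqlengths(gr) <- setNames(rep(cfg@chromLengthBp, length(chroms)), chroms)
    names(gr) <- sprintf("m%05d", seq_along(gr))
    gr
}

haldaneR <- function(dMorgan) 0.5 * (1 - exp(-2 * dMorgan))

## cumulative XOR of a 0/1 start vector with a 0/1 switch matrix, by column
mosaicAlleles <- function(startAllele, switches) {
    n <- length(startAllele)
    m <- ncol(switches) + 1L
    out <- matrix(0L, n, m)
    acc <- startAllele
    out[, 1L] <- acc
    if (m > 1L) for (j in 2:m) {
        acc <- (acc + switches[, j - 1L]) %% 2L
        out[, j] <- acc
    }
    out
}

#' Simulate genotypes of an F2 population
#'
#' Each individual is the sum of two independent gametes; each gamete is a
#' mosaic of the two parental haplotypes in which recombination between
#' adjacent markers occurs with the Haldane map-function probability
#' `r = (1 - exp(-2 d)) / 2`, `d` being the map distance in Morgans derived
#' from the physical distance and `recombRate` (cM/Mb). No crossover
#' interference is modelled. Allele 1 is the dwarf-parent allele.
#'
#' @param cfg a [SimConfig].
#' @param markers optional marker map (`GRanges`, width 1, non-decreasing
#'   positions within each chromosome); drawn with [simulateMarkerMap()]
#'   when `NULL`.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return an [F2Genotypes] object (`popSize` x markers dosage matrix).
#' @examples
#' geno <- simulateF2Population(SimConfig(nMarkersPerChrom = 50L), seed = 1)
#' table(dosages(geno))
#' @export
simulateF2Population <- function(cfg, markers = NULL, seed = NULL) {
    stopifnot(is(cfg, "SimConfig"))
    if (!is.null(seed)) set.seed(seed)
    if (is.null(markers)) markers <- simulateMarkerMap(cfg)
    chrom <- as.character(seqnames(markers))
    pos <- start(markers)
    bad <- unlist(lapply(split(pos, chrom), function(p) diff(p) < 0))
    if (any(bad))
        stop("marker positions must be non-decreasing within a chromosome")
    n <- cfg@popSize
    nGam <- 2L * n
    alleleCols <- vector("list", length(unique(chrom)))
    ord <- unique(chrom)
    dosage <- matrix(0L, n, length(markers))
    for (ch in ord) {
        idx <- which(chrom == ch)
        m <- length(idx)
        if (n == 0L || m == 0L) next
        dM <- diff(pos[idx]) / 1e6 * cfg@recombRate / 100
        r <- haldaneR(dM)
        startAllele <- matrix(rbinom(nGam, 1L, 0.5), nGam, 1L)[, 1L]
        switches <- if (m > 1L)
            matrix(rbinom(nGam * (m - 1L), 1L, rep(r, each = nGam)),
                   nGam, m - 1L)
        else matrix(0L, nGam, 0L)
        gam <- mosaicAlleles(startAllele, switches)
        dosage[, idx] <- gam[seq_len(n), , drop = FALSE] +
            gam[n + seq_len(n), , drop = FALSE]
    }
    if (n > 0L)
        rownames(dosage) <- sprintf("F2_%03d", seq_len(n))
    new("F2Genotypes", dosage = dosage, markers = markers)
}

#' Simulate a quantitative phenotype controlled by one major QTL
#'
#' `height_i = baseline + qtlEffect * dosage_i + qtlDominance * [dosage_i == 1]
#' + Normal(0, envSd)`, with the dosage taken at the marker nearest the
#' configured QTL position.
#'
#' @param geno an [F2Genotypes].
#' @param cfg the [SimConfig] used to generate `geno`.
#' @param seed optional integer seed.
#' @return named numeric vector of heights (cm), one per individual.
#' @export
simulatePhenotypes <- function(geno, cfg, seed = NULL) {
    stopifnot(is(geno, "F2Genotypes"), is(cfg, "SimConfig"))
    if (cfg@envSd < 0) stop("envSd must be >= 0")
    if (!is.null(seed)) set.seed(seed)
    qi <- qtlMarkerIndex(geno, cfg)
    d <- dosages(geno)[, qi]
    h <- cfg@baseline + cfg@qtlEffect * d + cfg@qtlDominance * (d == 1L) +
        rnorm(nrow(dosages(geno)), 0, cfg@envSd)
    setNames(h, rownames(dosages(geno)))
}

#' Index of the marker nearest the configured QTL
#' @keywords internal
qtlMarkerIndex <- function(geno, cfg) {
    mk <- markerRanges(geno)
    onChrom <- which(as.character(seqnames(mk)) == cfg@qtlChrom)
    if (!length(onChrom))
        stop("no marker on the QTL chromosome ", cfg@qtlChrom)
    onChrom[which.min(abs(start(mk)[onChrom] - cfg@qtlPosBp))]
}

#' Simulate pooled sequencing of the two extreme bulks
#'
#' For every marker and bulk, the true dwarf-allele frequency is the mean
#' dosage of the bulk members divided by two; read depth is
#' Poisson(`bulkDepthMean`) and the dwarf-allele read count is
#' Binomial(depth, `p (1 - e) + (1 - p) e`) with symmetric sequencing error
#' `e`. Parents are emitted as fixed opposite homozygotes (tall parent P1 =
#' reference allele, dwarf parent P2 = alternate) with
#' Poisson(`parentDepthMean`) depths.
#'
#' @param geno an [F2Genotypes].
#' @param bulks list with integer/character index vectors `low` and `high`
#'   (disjoint, each of length `bulkSize`), as returned by [selectBulks()].
#' @param cfg the [SimConfig].
#' @param genome optional `DNAStringSet`; when given, each marker's
#'   reference allele is the genome base at its position (so downstream
#'   effect classification sees consistent coordinates); otherwise ref
#'   bases are drawn at random.
#' @param seed optional integer seed.
#' @return `GRanges` of variant records with metadata columns `ref`, `alt`,
#'   `p1GT`, `p2GT`, `p1Depth`, `p2Depth`, `hbRef`, `hbAlt`, `lbRef`,
#'   `lbAlt` (high-/low-bulk reference and alternate read counts).
#' @export
simulateBulkReads <- function(geno, bulks, cfg, genome = NULL, seed = NULL) {
    stopifnot(is(geno, "F2Genotypes"), is(cfg, "SimConfig"))
    if (!is.list(bulks) || !all(c("low", "high") %in% names(bulks)))
        stop("bulks must be a list with elements 'low' and 'high'")
    if (length(bulks$low) == 0L || length(bulks$high) == 0L)
        stop("empty bulk set")
    ids <- rownames(dosages(geno))
    asIdx <- function(b) if (is.character(b)) match(b, ids) else as.integer(b)
    iLow <- asIdx(bulks$low); iHigh <- asIdx(bulks$high)
    if (anyNA(iLow) || anyNA(iHigh)) stop("unknown bulk member id")
    if (length(intersect(iLow, iHigh))) stop("bulk sets must be disjoint")
    if (!is.null(seed)) set.seed(seed)
    mk <- markerRanges(geno)
    m <- length(mk)
    dos <- dosages(geno)
    pLow <- colMeans(dos[iLow, , drop = FALSE]) / 2
    pHigh <- colMeans(dos[iHigh, , drop = FALSE]) / 2
    e <- cfg@seqError
    obsP <- function(p) p * (1 - e) + (1 - p) * e
    depthHigh <- rpois(m, cfg@bulkDepthMean)
    depthLow <- rpois(m, cfg@bulkDepthMean)
    altHigh <- rbinom(m, depthHigh, obsP(pHigh))
    altLow <- rbinom(m, depthLow, obsP(pLow))
    bases <- c("A", "C", "G", "T")
    ref <- if (is.null(genome)) sample(bases, m, replace = TRUE)
    else vapply(seq_len(m), function(i) {
        ch <- as.character(seqnames(mk))[i]
        as.character(Biostrings::subseq(genome[[ch]], start(mk)[i],
                                        start(mk)[i]))
    }, character(1))
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    out <- mk
    mcols(out) <- DataFrame(
        ref = ref, alt = unname(alt),
        p1GT = "0/0", p2GT = "1/1",
        p1Depth = rpois(m, cfg@parentDepthMean),
        p2Depth = rpois(m, cfg@parentDepthMean),
        hbRef = depthHigh - altHigh, hbAlt = altHigh,
        lbRef = depthLow - altLow, lbAlt = altLow)
    out
}

#' Simulate gene models and the matching chromosome sequence
#'
#' Places non-overlapping genes (one CDS per gene, length divisible by 3,
#' starting with ATG, both strands) on each chromosome and generates a
#' random chromosome sequence patched so that every CDS begins with a start
#' codon. Gene spans extend a fixed flank beyond the CDS so that gene-body
#' (non-coding) variants exist.
#'
#' @param cfg a [SimConfig].
#' @param nGenesPerChrom genes per chromosome.
#' @param cdsLenRange CDS length range in codons is derived from this bp
#'   range; lengths are rounded down to a multiple of 3.
#' @param utrFlank gene-span flank (bp) on each side of the CDS.
#' @param seed optional integer seed.
#' @return list with elements `models` (a [GeneModels]) and `genome`
#'   (a [Biostrings::DNAStringSet]).
#' @export
simulateGeneModels <- function(cfg, nGenesPerChrom = 25L,
                               cdsLenRange = c(600L, 1500L),
                               utrFlank = 200L, seed = NULL) {
    stopifnot(is(cfg, "SimConfig"))
    if (!is.null(seed)) set.seed(seed)
    chroms <- chromNames(cfg)
    L <- cfg@chromLengthBp
    genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
        character(1)))
    names(genome) <- chroms
    rows <- list()
    cdsList <- list()
    slot <- L %/% nGenesPerChrom
    k <- 0L
    for (ch in chroms) {
        for (g in seq_len(nGenesPerChrom)) {
            k <- k + 1L
            cdsLen <- sample(seq(cdsLenRange[1], cdsLenRange[2]), 1L)
            cdsLen <- cdsLen - cdsLen %% 3L
            lo <- (g - 1L) * slot + utrFlank + 1L
            hi <- g * slot - utrFlank - cdsLen
            if (hi <= lo) next
            cdsStart <- sample(lo:hi, 1L)
            cdsEnd <- cdsStart + cdsLen - 1L
            strand <- sample(c("+", "-"), 1L)
            id <- sprintf("gene%03d", k)
            rows[[id]] <- data.frame(
                chrom = ch, start = max(1L, cdsStart - utrFlank),
                end = min(L, cdsEnd + utrFlank), strand = strand,
                geneId = id)
            cdsList[[id]] <- GRanges(ch, IRanges(cdsStart, cdsEnd),
                                     strand = strand)
            ## patch the chromosome so the CDS begins with ATG
            if (strand == "+") {
                Biostrings::subseq(genome[[ch]], cdsStart, cdsStart + 2L) <-
                    Biostrings::DNAString("ATG")
            } else {
                Biostrings::subseq(genome[[ch]], cdsEnd - 2L, cdsEnd) <-
                    Biostrings::DNAString("CAT")
            }
        }
    }
    geneDf <- do.call(rbind, rows)
    geneGr <- GRanges(geneDf$chrom, IRanges(geneDf$start, geneDf$end),
                      strand = geneDf$strand)
    mcols(geneGr)$geneId <- geneDf$geneId
    seqlengths(geneGr) <- setNames(rep(L, length(chroms)), chroms)
    models <- new("GeneModels", genes = geneGr,
                  cds = GRangesList(cdsList))
    list(models = models, genome = genome)
}

#' Simulate an RNA-seq count matrix with planted differential expression
#'
#' Counts are negative-binomial with `var = mu + dispersion * mu^2`
#' (`rnbinom` with `size = 1/dispersion`); the Poisson limit is used when
#' `dispersion = 0`. Condition means are `mu_g` for the control and
#' `mu_g * 2^log2fc` for the treatment, with per-gene `log2fc` taken from
#' `dePlan` (0 for unlisted genes).
#'
#' @param geneIds character vector of gene ids (or a [GeneModels]).
#' @param dePlan data.frame with columns `geneId` and `log2fc`; the planted
#'   truth. May be empty.
#' @param nReps replicates per condition (>= 1).
#' @param dispersion NB dispersion alpha (>= 0).
#' @param baseMeanRange log10 range from which per-gene control means are
#'   drawn (uniform on the log scale).
#' @param seed optional integer seed.
#' @return integer matrix genes x samples, samples named
#'   `tall_1..n, dwarf_1..n`, with the realised plan in
#'   `attr(, "dePlan")` and control means in `attr(, "mu")`.
#' @export
simulateRnaseqCounts <- function(geneIds, dePlan = NULL, nReps = 3L,
                                 dispersion = 0.05,
                                 baseMeanRange = c(1, 3), seed = NULL) {
    if (is(geneIds, "GeneModels"))
        geneIds <- mcols(geneRanges(geneIds))$geneId
    if (nReps < 1L) stop("nReps must be >= 1 per condition")
    if (dispersion < 0) stop("dispersion must be >= 0")
    if (!is.null(seed)) set.seed(seed)
    g <- length(geneIds)
    lfc <- setNames(numeric(g), geneIds)
    if (!is.null(dePlan) && nrow(dePlan)) {
        if (!all(dePlan$geneId %in% geneIds))
            stop("dePlan gene not in geneIds")
        lfc[dePlan$geneId] <- dePlan$log2fc
    }
    mu <- 10^runif(g, baseMeanRange[1], baseMeanRange[2])
    draw <- function(m) {
        if (dispersion == 0) rpois(g, m) else rnbinom(g, mu = m, size = 1 / dispersion)
    }
    tall <- matrix(vapply(seq_len(nReps), function(i) draw(mu),
                          numeric(g)), nrow = g)
    dwarf <- matrix(vapply(seq_len(nReps), function(i) draw(mu * 2^lfc),
                           numeric(g)), nrow = g)
    counts <- cbind(tall, dwarf)
    dimnames(counts) <- list(geneIds,
                             c(paste0("tall_", seq_len(nReps)),
                               paste0("dwarf_", seq_len(nReps))))
    storage.mode(counts) <- "integer"
    attr(counts, "dePlan") <- data.frame(geneId = geneIds, log2fc = unname(lfc))
    attr(counts, "mu") <- mu
    counts
}
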