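#' FPKM expression matrix
#'
#' `fpkm = counts * 1e9 / (geneLength_bp * librarySize)`, the classical
#' fragments-per-kilobase-per-million normalisation used to flag whether a
#' gene is expressed at all (`FPKM > 1` in at least one sample).
#'
#' @param counts integer matrix, genes x samples.
#' @param geneLengths gene lengths in bp (> 0), recycled along rows; named
#'   vectors are matched to rownames.
#' @param librarySizes per-sample total mapped counts; defaults to column
#'   sums. Zero library sizes are an error.
#' @return numeric matrix of FPKM values, same dimensions as `counts`.
#' @examples
#' computeFpkm(matrix(100), geneLengths = 1000, librarySizes = 1e6)  # 100
#' @export
computeFpkm <- function(counts, geneLengths, librarySizes = colSums(counts)) {
    counts <- as.matrix(counts)
    if (!is.null(names(geneLengths)) && !is.null(rownames(counts)))
        geneLengths <- geneLengths[rownames(counts)]
    if (any(geneLengths <= 0) || anyNA(geneLengths))
        stop("gene lengths must be > 0")
    if (any(librarySizes == 0))
        stop("zero library size")
    sweep(counts * 1e9 / geneLengths, 2, librarySizes, "/")
}

#' Median-of-ratios size factors
#'
#' The DESeq-style normalisation: a pseudo-reference sample is built as the
#' gene-wise geometric mean across samples, and each sample's size factor
#' is the median over genes (restricted to genes with positive counts in
#' every sample) of its ratio to that reference.
#'
#' @param counts integer matrix, genes x samples.
#' @return named numeric vector of size factors.
#' @export
sizeFactors <- function(counts) {
    counts <- as.matrix(counts)
    allPos <- rowSums(counts <= 0) == 0
    if (!any(allPos))
        stop("no gene with positive counts in all samples")
    k <- counts[allPos, , drop = FALSE]
    logGeoMean <- rowMeans(log(k))
    sf <- apply(k, 2, function(col) exp(median(log(col) - logGeoMean)))
    setNames(sf, colnames(counts))
}

#' Minimal negative-binomial Wald test for two-group differential expression
#'
#' A deliberately small count-based test: per gene, normalized group means
#' are compared on the log2 scale with a Wald statistic whose variance
#' comes from the NB relation `var = mu + alpha mu^2`; the dispersion
#' `alpha` is a per-gene method-of-moments estimate pooled across the two
#' groups, then moderated toward the across-gene median with `priorDf`
#' pseudo-degrees of freedom (floored at 1e-8), and a 0.5 pseudo-count
#' stabilises the fold change of low-count genes. The statistic is
#' referred to a t distribution with `n1 + n2 - 2 + priorDf` degrees of
#' freedom, reflecting the information content of the moderated variance.
#' The moderation is essential with 2-4 replicates: a raw per-gene moment
#' estimate is so noisy that either the type-I error inflates (normal
#' reference) or strongly-changed genes cannot reach small p-values (a
#' t with 4 df has no usable tail). There is no outlier handling or
#' independent filtering.
#'
#' @param counts integer matrix, genes x samples.
#' @param groups factor (2 levels) or character vector over samples; the
#'   first level is the control/reference (denominator of the fold change).
#' @param sf size factors; computed with [sizeFactors()] when `NULL`.
#' @param priorDf weight (pseudo-df) of the across-gene median dispersion
#'   in the moderated per-gene estimate; 0 disables moderation.
#' @return `data.frame`: `geneId`, `baseMean` (mean normalized count),
#'   `log2FoldChange` (treatment over control), `lfcSE`, `stat`, `pvalue`.
#' @export
nbTest <- function(counts, groups, sf = NULL, priorDf = 10) {
    counts <- as.matrix(counts)
    groups <- as.factor(groups)
    if (nlevels(groups) != 2L)
        stop("groups must have exactly 2 levels")
    if (any(table(groups) < 2L))
        stop("each group needs at least 2 replicates")
    if (is.null(sf)) sf <- sizeFactors(counts)
    y <- sweep(counts, 2, sf, "/")
    iA <- groups == levels(groups)[1]   # control
    iB <- !iA
    nA <- sum(iA); nB <- sum(iB)
    mA <- rowMeans(y[, iA, drop = FALSE])
    mB <- rowMeans(y[, iB, drop = FALSE])
    vA <- apply(y[, iA, drop = FALSE], 1, var)
    vB <- apply(y[, iB, drop = FALSE], 1, var)
    cA <- mean(1 / sf[iA])   # shot-noise scale of normalized counts
    cB <- mean(1 / sf[iB])
    ## per-group moment estimates of alpha, pooled by residual df
    alphaOf <- function(v, m, cc) ifelse(m > 0, (v - m * cc) / m^2, NA_real_)
    aA <- alphaOf(vA, mA, cA)
    aB <- alphaOf(vB, mB, cB)
    wA <- ifelse(is.na(aA), 0, nA - 1)
    wB <- ifelse(is.na(aB), 0, nB - 1)
    alphaRaw <- ifelse(wA + wB > 0,
                       (ifelse(is.na(aA), 0, aA) * wA +
                        ifelse(is.na(aB), 0, aB) * wB) / (wA + wB),
                       NA_real_)
    ## moderate the noisy per-gene estimate toward the across-gene median
    alpha0 <- median(alphaRaw, na.rm = TRUE)
    if (!is.finite(alpha0)) alpha0 <- 0
    dg <- nA + nB - 2
    alpha <- ifelse(is.na(alphaRaw), alpha0,
                    (dg * alphaRaw + priorDf * alpha0) / (dg + priorDf))
    alpha <- pmax(alpha, 1e-8)
    varMeanA <- (mA * cA + alpha * mA^2) / nA
    varMeanB <- (mB * cB + alpha * mB^2) / nB
    lfc <- log2((mB + 0.5) / (mA + 0.5))
    se <- sqrt(varMeanA / (mA + 0.5)^2 + varMeanB / (mB + 0.5)^2) / log(2)
    stat <- ifelse(se > 0, lfc / se, 0)
    p <- 2 * stats::pt(-abs(stat), df = dg + priorDf)
    p[se == 0] <- 1
    data.frame(geneId = rownames(counts) %||% as.character(seq_len(nrow(counts))),
               baseMean = rowMeans(y),
               log2FoldChange = lfc, lfcSE = se, stat = stat, pvalue = p,
               row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH FDR adjustment (monotone, capped at 1), delegated to
#' [stats::p.adjust()]. Out-of-range p-values are an error rather than
#' silently clipped.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bhAdjust <- function(p) {
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Flags a gene as a DEG when `|log2FoldChange| > lfcMin` and `q < qMax`
#' (both strict, so a gene at exactly the boundary is not called).
#' Direction is the sign of the fold change with the control group as
#' denominator: `up` = higher in the treatment (dwarf) samples. When an
#' FPKM matrix is supplied, `expressed` marks genes with FPKM >
#' `fpkmMin` in at least one sample; the flag is reported but not used to
#' prefilter DEG calls.
#'
#' @param res `data.frame` from [nbTest()].
#' @param fpkm optional FPKM matrix with rownames matching `geneId`.
#' @param lfcMin,qMax,fpkmMin thresholds (defaults 1, 0.05, 1).
#' @return `res` with added columns `q`, `deg`, `direction`
#'   (`up`/`down`/`none`) and, when FPKM is given, `expressed`.
#' @export
callDegs <- function(res, fpkm = NULL, lfcMin = 1, qMax = 0.05, fpkmMin = 1) {
    res$q <- bhAdjust(res$pvalue)
    res$deg <- abs(res$log2FoldChange) > lfcMin & res$q < qMax
    res$direction <- ifelse(!res$deg, "none",
                            ifelse(res$log2FoldChange > 0, "up", "down"))
    if (!is.null(fpkm)) {
        expressed <- apply(fpkm > fpkmMin, 1, any)
        res$expressed <- unname(expressed[res$geneId])
    }
    res
}

#' Hypergeometric gene-set enrichment
#'
#' For every term, the upper-tail hypergeometric probability of observing
#' at least the seen overlap between the DEG set and the term's genes,
#' given the universe; BH-adjusted across terms, significant at
#' `FDR <= 0.05`.
#'
#' @param degSet character vector of DEG ids (non-empty, a subset of
#'   `universe`).
#' @param universe character vector of all testable gene ids.
#' @param termMap `data.frame` with columns `term` and `geneId` (or first
#'   two columns in that order).
#' @return `data.frame`: `term`, `termSize` (in universe), `overlap`,
#'   `pvalue`, `q`, `significant`, sorted by p-value.
#' @export
hypergeometricEnrichment <- function(degSet, universe, termMap) {
    if (length(degSet) == 0) stop("empty DEG set")
    if (!all(degSet %in% universe))
        stop("degSet must be a subset of universe")
    if (!all(c("term", "geneId") %in% colnames(termMap)))
        colnames(termMap)[1:2] <- c("term", "geneId")
    termMap <- termMap[termMap$geneId %in% universe, , drop = FALSE]
    N <- length(unique(universe))
    n <- length(unique(degSet))
    byTerm <- split(termMap$geneId, termMap$term)
    rows <- lapply(names(byTerm), function(tm) {
        K <- length(unique(byTerm[[tm]]))
        ov <- length(intersect(byTerm[[tm]], degSet))
        p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(term = tm, termSize = K, overlap = ov, pvalue = p)
    })
    out <- do.call(rbind, rows)
    out$q <- bhAdjust(out$pvalue)
    out$significant <- out$q <= 0.05
    out[order(out$pvalue), , drop = FALSE]
}

#' Sample-sample Pearson correlation of log expression
#'
#' Pearson correlation between samples on `log2(normalized count + 1)`,
#' the usual RNA-seq replicate-quality check (replicates should correlate
#' near 1, conditions separate).
#'
#' @param counts integer matrix, genes x samples (>= 2 samples).
#' @param sf size factors; computed when `NULL`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sampleCorrelation <- function(counts, sf = NULL) {
    counts <- as.matrix(counts)
    if (ncol(counts) < 2L) stop("need at least 2 samples")
    if (is.null(sf)) sf <- sizeFactors(counts)
    x <- log2(sweep(counts, 2, sf, "/") + 1)
    if (any(apply(x, 2, sd) == 0)) stop("zero-variance sample")
    cor(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((ctTarget - ctRef) - (ctTargetControl - ctRefControl))`: target-gene
#' qPCR threshold cycles double-normalised to a reference gene and to the
#' control condition, whose relative expression is 1 by construction.
#'
#' @param ctTarget,ctRef Ct of the target and reference gene in the sample.
#' @param ctTargetControl,ctRefControl same in the control condition.
#' @return relative expression (fold change versus the control).
#' @examples
#' ddct(25, 20, 24, 20)  # 0.5
#' @export
ddct <- function(ctTarget, ctRef, ctTargetControl, ctRefControl) {
    stopifnot(all(is.finite(c(ctTarget, ctRef, ctTargetControl,
                              ctRefControl))))
    2^-((ctTarget - ctRef) - (ctTargetControl - ctRefControl))
}
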