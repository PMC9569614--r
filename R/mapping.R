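## marker-count classes used to stratify permutation thresholds: window
## precision scales with marker density, so pooling all windows would give
## thresholds too wide for dense windows and too narrow for sparse ones.
MARKER_CLASS_BREAKS <- c(2, 5, 10, 20, Inf)
MARKER_CLASS_LABELS <- c("3-5", "6-10", "11-20", ">20")

markerClass <- function(n) {
    cut(n, breaks = MARKER_CLASS_BREAKS, labels = MARKER_CLASS_LABELS,
        right = TRUE)
}

## sliding windows for one set of chromosome lengths; full windows only
tileWindows <- function(chromLens, windowBp, stepBp) {
    chromLens <- unlist(chromLens)
    starts <- lapply(names(chromLens), function(ch) {
        lastStart <- max(1L, chromLens[[ch]] - windowBp + 1L)
        seq.int(1L, lastStart, by = stepBp)
    })
    ans <- GRanges(rep(names(chromLens), lengths(starts)),
                   IRanges(unlist(starts), width = windowBp))
    seqlengths(ans) <- chromLens
    ans
}

## sparse marker x window incidence matrix (marker in window iff
## start <= pos <= end)
markerWindowIncidence <- function(track, windows) {
    hits <- findOverlaps(track, windows)
    Matrix::sparseMatrix(i = S4Vectors::queryHits(hits),
                         j = S4Vectors::subjectHits(hits),
                         x = 1,
                         dims = c(length(track), length(windows)))
}

#' Sliding-window SNP-index and delta(SNP-index) profile
#'
#' Slides a fixed window (default 20 kb) along each chromosome in fixed
#' steps (default 2 kb) and averages, without depth weighting, the member
#' markers' per-bulk SNP-index and per-marker delta. A marker belongs to a
#' window iff `start <= pos <= end`. Windows with fewer than `minMarkers`
#' markers are masked (`NA` means, never zero).
#'
#' @param track a filtered [SnpIndexTrack] (no missing indices).
#' @param windowBp window size in bp.
#' @param stepBp step between window starts in bp; must not exceed
#'   `windowBp` (a larger step would leave markers uncovered).
#' @param minMarkers windows with fewer markers are masked.
#' @return a [WindowProfile]; thresholds are `NA` until
#'   [permutationThreshold()] is run.
#' @export
windowProfile <- function(track, windowBp = 20000L, stepBp = 2000L,
                          minMarkers = 3L) {
    stopifnot(is(track, "SnpIndexTrack"))
    if (stepBp > windowBp)
        stop("stepBp must not exceed windowBp (markers would fall in gaps)")
    mc <- mcols(track)
    if (anyNA(mc$indexHigh) || anyNA(mc$indexLow))
        stop("track contains missing indices; run filterMarkers() first")
    sl <- seqlengths(track)
    if (anyNA(sl)) {
        ext <- vapply(split(end(track), as.character(seqnames(track))),
                      max, numeric(1))
        sl[names(ext)] <- pmax(sl[names(ext)], ext, na.rm = TRUE)
    }
    sl <- sl[!is.na(sl)]
    windows <- tileWindows(as.list(sl), as.integer(windowBp),
                           as.integer(stepBp))
    A <- markerWindowIncidence(track, windows)
    n <- Matrix::colSums(A)
    wmean <- function(v) {
        s <- as.vector(Matrix::crossprod(A, v))
        ifelse(n > 0, s / n, NA_real_)
    }
    meanHigh <- wmean(mc$indexHigh)
    meanLow <- wmean(mc$indexLow)
    meanDelta <- wmean(mc$delta)
    masked <- n < minMarkers
    meanHigh[masked] <- NA_real_
    meanLow[masked] <- NA_real_
    meanDelta[masked] <- NA_real_
    mcols(windows) <- DataFrame(
        nMarkers = as.integer(n),
        meanIndexHigh = meanHigh, meanIndexLow = meanLow,
        meanDelta = meanDelta,
        thresholdLo = NA_real_, thresholdHi = NA_real_)
    out <- new("WindowProfile", windows)
    metadata(out) <- list(windowBp = as.integer(windowBp),
                          stepBp = as.integer(stepBp),
                          minMarkers = as.integer(minMarkers))
    out
}

#' Fill the windowed delta(SNP-index) from the per-bulk means
#'
#' The windowed delta is the unweighted mean over member markers of the
#' per-marker `indexHigh - indexLow`; because every window averages the
#' same marker set for both bulks this equals
#' `meanIndexHigh - meanIndexLow`, which is what this helper (re)computes.
#' Swapping the bulks negates the profile exactly.
#'
#' @param profile a [WindowProfile].
#' @return the profile with `meanDelta` filled.
#' @export
deltaProfile <- function(profile) {
    stopifnot(is(profile, "WindowProfile"))
    mcols(profile)$meanDelta <-
        mcols(profile)$meanIndexHigh - mcols(profile)$meanIndexLow
    profile
}

#' Null thresholds for the windowed delta(SNP-index)
#'
#' Builds the null distribution of the windowed delta by replaying, for
#' each of `nPerm` replicates, the two sampling stages that generate a
#' bulk's SNP-index in the absence of a trait-linked locus: (1)
#' bulk-composition sampling -- each pseudo-bulk's allele frequency is a
#' Binomial(2 x `bulkSize`, p) draw around the window's pooled read
#' frequency, shared by all markers of the window because markers 20 kb
#' apart in an F2 are essentially completely linked -- and (2) read
#' sampling, a Binomial draw at every member marker's observed depth. At
#' typical QTL-seq depths the first stage dominates the null variance, so
#' a read-only label permutation would be badly anticonservative.
#' Two-sided `level` quantiles of the null are taken, stratified by window
#' marker-count class (3-5, 6-10, 11-20, >20 markers) because window
#' precision varies with marker density; all null values of a class are
#' pooled.
#'
#' @param track the filtered [SnpIndexTrack] used to build `profile`.
#' @param profile the [WindowProfile] to annotate.
#' @param nPerm number of null replicates (default 1000); fewer than 100
#'   triggers a warning (thresholds become unstable).
#' @param level two-sided confidence level (default 0.95, i.e. the 2.5th
#'   and 97.5th null percentiles); `level >= 1` yields infinite thresholds
#'   so that nothing is called significant.
#' @param bulkSize number of individuals pooled in each bulk (default 30).
#' @param seed optional integer seed; identical seeds give identical
#'   thresholds.
#' @return `profile` with `thresholdLo`/`thresholdHi` filled (`NA` for
#'   masked windows) and the null settings recorded in
#'   `metadata()$permutation`.
#' @export
permutationThreshold <- function(track, profile, nPerm = 1000L,
                                 level = 0.95, bulkSize = 30L,
                                 seed = NULL) {
    stopifnot(is(track, "SnpIndexTrack"), is(profile, "WindowProfile"))
    if (nPerm < 100L)
        warning("nPerm < 100: permutation thresholds will be unstable")
    if (!is.null(seed)) set.seed(seed)
    mc <- mcols(track)
    if (anyNA(mc$indexHigh) || anyNA(mc$indexLow))
        stop("track contains missing indices; run filterMarkers() first")
    nW <- length(profile)
    lo <- rep(NA_real_, nW)
    hi <- rep(NA_real_, nW)
    nMk <- mcols(profile)$nMarkers
    minMk <- metadata(profile)$minMarkers %||% 1L
    cls <- markerClass(nMk)
    unmasked <- !is.na(mcols(profile)$meanDelta)
    if (level >= 1) {
        lo[unmasked] <- -Inf
        hi[unmasked] <- Inf
    } else {
        hits <- findOverlaps(track, granges(profile))
        winOf <- S4Vectors::subjectHits(hits)
        mkOf <- S4Vectors::queryHits(hits)
        keep <- unmasked[winOf]
        winOf <- winOf[keep]
        mkOf <- mkOf[keep]
        dH <- mc$depthHigh[mkOf]
        dL <- mc$depthLow[mkOf]
        ## pooled dwarf-allele read frequency per window (markers within a
        ## window share it: they are completely linked at this scale)
        pooled <- (mc$dwarfHigh + mc$dwarfLow)[mkOf]
        depth <- dH + dL
        pBar <- rowsum(as.numeric(pooled), winOf) /
            rowsum(as.numeric(depth), winOf)
        wIdx <- match(winOf, as.integer(rownames(pBar)))
        wList <- sort(unique(winOf))
        nIncid <- length(winOf)
        nUW <- length(wList)
        twoN <- 2L * as.integer(bulkSize)
        nullByWin <- matrix(NA_real_, nUW, nPerm)
        chunk <- max(1L, min(nPerm, as.integer(2e6 / max(1, nIncid))))
        done <- 0L
        invMk <- 1 / nMk[wList]
        while (done < nPerm) {
            k <- min(chunk, nPerm - done)
            ## stage 1: bulk composition, one frequency per window & replicate
            pH <- matrix(rbinom(nUW * k, twoN, pBar[, 1]) / twoN, nUW, k)
            pL <- matrix(rbinom(nUW * k, twoN, pBar[, 1]) / twoN, nUW, k)
            ## stage 2: read sampling at the observed per-marker depths
            aH <- matrix(rbinom(nIncid * k, dH, pH[wIdx, ]), nIncid, k)
            aL <- matrix(rbinom(nIncid * k, dL, pL[wIdx, ]), nIncid, k)
            dsum <- rowsum(aH / dH - aL / dL, winOf)
            nullByWin[, done + seq_len(k)] <- dsum * invMk
            done <- done + k
        }
        alpha <- 1 - level
        clsU <- cls[wList]
        for (cl in levels(cls)) {
            rows <- which(clsU == cl & nMk[wList] >= minMk)
            if (!length(rows)) next
            qs <- quantile(nullByWin[rows, , drop = FALSE],
                           c(alpha / 2, 1 - alpha / 2), names = FALSE)
            lo[wList[rows]] <- qs[1]
            hi[wList[rows]] <- qs[2]
        }
    }
    mcols(profile)$thresholdLo <- lo
    mcols(profile)$thresholdHi <- hi
    metadata(profile)$permutation <- list(
        nPerm = as.integer(nPerm), level = level,
        bulkSize = as.integer(bulkSize),
        scheme = "two-stage null: bulk-composition + read sampling at observed depths",
        sided = "two-sided, stratified by window marker-count class")
    profile
}

#' Call candidate QTL regions from a thresholded window profile
#'
#' A window is significant when its mean delta(SNP-index) falls strictly
#' outside `[thresholdLo, thresholdHi]`. Overlapping or abutting
#' significant windows are merged; each region spans from the first merged
#' window start to the last merged window end (clipped to the chromosome)
#' and carries its significant-window count and, when `track` is supplied,
#' its member marker ids.
#'
#' @param profile a [WindowProfile] with thresholds.
#' @param track optional [SnpIndexTrack]; member markers are attached.
#' @return `GRanges` of candidate regions with metadata columns
#'   `nSignificantWindows`, `peakDelta` and (optionally) `markerIds`
#'   (a `CharacterList`). Empty when no window is significant.
#' @export
callCandidateRegions <- function(profile, track = NULL) {
    stopifnot(is(profile, "WindowProfile"))
    mc <- mcols(profile)
    if (all(is.na(mc$thresholdLo) & is.na(mc$thresholdHi)))
        stop("run permutationThreshold() before calling regions")
    sig <- !is.na(mc$meanDelta) & !is.na(mc$thresholdLo) &
        (mc$meanDelta < mc$thresholdLo | mc$meanDelta > mc$thresholdHi)
    if (!any(sig)) {
        empty <- GRanges()
        mcols(empty) <- DataFrame(nSignificantWindows = integer(),
                                  peakDelta = numeric())
        return(empty)
    }
    sigW <- granges(profile)[sig]
    regions <- reduce(sigW, min.gapwidth = 1L)
    regions <- GenomicRanges::trim(regions)
    hits <- findOverlaps(sigW, regions)
    nSig <- tabulate(S4Vectors::subjectHits(hits), nbins = length(regions))
    dperW <- mc$meanDelta[sig]
    peak <- vapply(seq_along(regions), function(i) {
        d <- dperW[S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == i]]
        d[which.max(abs(d))]
    }, numeric(1))
    mcols(regions) <- DataFrame(nSignificantWindows = nSig, peakDelta = peak)
    if (!is.null(track)) {
        mhits <- findOverlaps(track, regions)
        ids <- names(track) %||% as.character(seq_along(track))
        mcols(regions)$markerIds <- S4Vectors::splitAsList(
            ids[S4Vectors::queryHits(mhits)],
            factor(S4Vectors::subjectHits(mhits), levels = seq_along(regions)))
    }
    regions
}

#' Plot a delta(SNP-index) profile with its threshold band
#'
#' One base-graphics panel per chromosome: windowed delta in black, the
#' permutation threshold band in blue, candidate regions shaded.
#'
#' @param profile a [WindowProfile].
#' @param regions optional `GRanges` of candidate regions.
#' @export
plotDeltaProfile <- function(profile, regions = NULL) {
    stopifnot(is(profile, "WindowProfile"))
    chroms <- unique(as.character(seqnames(profile)))
    op <- graphics::par(mfrow = c(length(chroms), 1),
                        mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    mid <- (start(profile) + end(profile)) / 2
    for (ch in chroms) {
        i <- as.character(seqnames(profile)) == ch
        graphics::plot(mid[i] / 1e6, mcols(profile)$meanDelta[i], type = "l",
                       xlab = paste(ch, "(Mb)"),
                       ylab = expression(Delta * "(SNP-index)"),
                       ylim = c(-1, 1), main = ch)
        graphics::lines(mid[i] / 1e6, mcols(profile)$thresholdLo[i],
                        col = "blue", lty = 2)
        graphics::lines(mid[i] / 1e6, mcols(profile)$thresholdHi[i],
                        col = "blue", lty = 2)
        graphics::abline(h = 0, col = "grey")
        if (!is.null(regions) && length(regions)) {
            ri <- as.character(seqnames(regions)) == ch
            if (any(ri))
                graphics::rect(start(regions)[ri] / 1e6, -1,
                               end(regions)[ri] / 1e6, 1,
                               col = grDevices::adjustcolor("red", 0.15),
                               border = NA)
        }
    }
    invisible(NULL)
}
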