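test_that("window means equal brute-force per-window averaging", {
    tr <- makeRandomTrack(500, chromLen = 200000L, seed = 13)
    pr <- windowProfile(tr, windowBp = 20000L, stepBp = 2000L,
                        minMarkers = 3L)
    mc <- S4Vectors::mcols(pr)
    pos <- GenomicRanges::start(tr)
    iH <- snpIndexHigh(tr); iL <- snpIndexLow(tr); dl <- snpDelta(tr)
    for (w in seq_along(pr)) {
        s <- GenomicRanges::start(pr)[w]; e <- GenomicRanges::end(pr)[w]
        expect_identical(e - s + 1L, 20000L)
        inW <- pos >= s & pos <= e
        expect_identical(mc$nMarkers[w], sum(inW))
        if (sum(inW) >= 3) {
            expect_equal(mc$meanIndexHigh[w], mean(iH[inW]))
            expect_equal(mc$meanIndexLow[w], mean(iL[inW]))
            expect_equal(mc$meanDelta[w], mean(dl[inW]))
        } else {
            expect_true(is.na(mc$meanDelta[w]))   # masked, never zero
        }
    }
    ## consecutive starts step by stepBp within a chromosome
    expect_true(all(diff(GenomicRanges::start(pr)) == 2000L))
})

test_that("single-marker windows reproduce that marker and steps respect bounds", {
    df <- data.frame(chrom = "chr1", pos = 10000L,
                     hbRef = 5L, hbAlt = 15L, lbRef = 15L, lbAlt = 5L)
    gr <- makeVariants(df)
    GenomeInfoDb::seqlengths(gr) <- c(chr1 = 40000L)
    tr <- computeSnpIndex(gr)
    pr <- windowProfile(tr, windowBp = 20000L, stepBp = 2000L,
                        minMarkers = 1L)
    mc <- S4Vectors::mcols(pr)
    covered <- mc$nMarkers == 1L
    expect_true(any(covered))
    expect_true(all(mc$meanIndexHigh[covered] == 0.75))
    expect_true(all(is.na(mc$meanDelta[!covered])))

    expect_error(windowProfile(tr, windowBp = 1000L, stepBp = 2000L),
                 "stepBp")
})

test_that("windowed delta is the bulk-mean difference and is antisymmetric", {
    tr <- makeRandomTrack(300, seed = 14)
    pr <- deltaProfile(windowProfile(tr))
    mc <- S4Vectors::mcols(pr)
    expect_equal(mc$meanDelta, mc$meanIndexHigh - mc$meanIndexLow)

    ## identical bulks: delta exactly zero
    df <- data.frame(chrom = "chr1", pos = (1:50) * 1000L,
                     hbRef = 10L, hbAlt = 10L, lbRef = 10L, lbAlt = 10L)
    tr0 <- computeSnpIndex(makeVariants(df))
    pr0 <- windowProfile(tr0, minMarkers = 1L)
    expect_true(all(S4Vectors::mcols(pr0)$meanDelta == 0, na.rm = TRUE))

    ## swapping the bulks negates the windowed delta exactly
    swapped <- makeVariants(data.frame(
        chrom = as.character(GenomicRanges::seqnames(tr)),
        pos = GenomicRanges::start(tr),
        hbRef = S4Vectors::mcols(tr)$depthLow - S4Vectors::mcols(tr)$dwarfLow,
        hbAlt = S4Vectors::mcols(tr)$dwarfLow,
        lbRef = S4Vectors::mcols(tr)$depthHigh - S4Vectors::mcols(tr)$dwarfHigh,
        lbAlt = S4Vectors::mcols(tr)$dwarfHigh))
    GenomeInfoDb::seqlengths(swapped) <- GenomeInfoDb::seqlengths(tr)
    prS <- windowProfile(computeSnpIndex(swapped))
    expect_equal(S4Vectors::mcols(prS)$meanDelta,
                 -S4Vectors::mcols(pr)$meanDelta)
})

test_that("null thresholds are seeded-deterministic and level 1 calls nothing", {
    tr <- makeRandomTrack(400, seed = 15)
    pr <- windowProfile(tr)
    a <- permutationThreshold(tr, pr, nPerm = 200L, bulkSize = 30L, seed = 42)
    b <- permutationThreshold(tr, pr, nPerm = 200L, bulkSize = 30L, seed = 42)
    expect_identical(S4Vectors::mcols(a)$thresholdLo,
                     S4Vectors::mcols(b)$thresholdLo)
    expect_identical(S4Vectors::mcols(a)$thresholdHi,
                     S4Vectors::mcols(b)$thresholdHi)

    full <- permutationThreshold(tr, pr, nPerm = 200L, level = 1,
                                 bulkSize = 30L, seed = 1)
    expect_identical(length(callCandidateRegions(full)), 0L)

    expect_warning(permutationThreshold(tr, pr, nPerm = 50L,
                                        bulkSize = 30L, seed = 1),
                   "unstable")
})

test_that("overlapping significant windows merge into one spanning region", {
    ## hand-built profile: three overlapping significant windows + one
    ## separate significant window + insignificant background
    win <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(c(1, 2001, 4001, 20001, 50001),
                                 width = 10000L))
    S4Vectors::mcols(win) <- S4Vectors::DataFrame(
        nMarkers = 5L,
        meanIndexHigh = 0.5, meanIndexLow = 0.5,
        meanDelta = c(0.8, 0.7, 0.9, 0.1, -0.9),
        thresholdLo = -0.5, thresholdHi = 0.5)
    pr <- new("WindowProfile", win)
    S4Vectors::metadata(pr) <- list(windowBp = 10000L, stepBp = 2000L,
                                    minMarkers = 3L)
    regions <- callCandidateRegions(pr)
    expect_identical(length(regions), 2L)
    expect_identical(GenomicRanges::start(regions), c(1L, 50001L))
    expect_identical(GenomicRanges::end(regions), c(14000L, 60000L))
    expect_identical(S4Vectors::mcols(regions)$nSignificantWindows,
                     c(3L, 1L))
    expect_equal(S4Vectors::mcols(regions)$peakDelta, c(0.9, -0.9))

    ## interval-merge oracle on a random significance pattern
    set.seed(16)
    n <- 200
    win2 <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(1L + (0:(n - 1)) * 2000L, width = 20000L))
    delta <- rnorm(n, 0, 0.3)
    S4Vectors::mcols(win2) <- S4Vectors::DataFrame(
        nMarkers = 10L, meanIndexHigh = 0.5, meanIndexLow = 0.5,
        meanDelta = delta, thresholdLo = -0.45, thresholdHi = 0.45)
    pr2 <- new("WindowProfile", win2)
    S4Vectors::metadata(pr2) <- list(windowBp = 20000L, stepBp = 2000L,
                                     minMarkers = 3L)
    got <- callCandidateRegions(pr2)
    ## brute force: mark significant bases, then find runs
    sig <- abs(delta) > 0.45
    if (any(sig)) {
        covered <- rep(FALSE, 2100000)
        for (i in which(sig))
            covered[GenomicRanges::start(win2)[i]:GenomicRanges::end(win2)[i]] <- TRUE
        runs <- rle(covered)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1L
        expStarts <- starts[runs$values]
        expEnds <- ends[runs$values]
        expect_identical(GenomicRanges::start(got), as.integer(expStarts))
        expect_identical(GenomicRanges::end(got), as.integer(expEnds))
    } else {
        expect_identical(length(got), 0L)
    }
})

test_that("regions never leave the chromosome and carry their markers", {
    tr <- makeRandomTrack(400, chromLen = 150000L, seed = 17)
    ## inflate the high-bulk index in one interval to force a region
    mc <- S4Vectors::mcols(tr)
    hot <- GenomicRanges::start(tr) >= 60000 & GenomicRanges::start(tr) <= 90000
    mc$dwarfHigh[hot] <- mc$depthHigh[hot]
    mc$indexHigh[hot] <- 1
    mc$delta[hot] <- 1 - mc$indexLow[hot]
    S4Vectors::mcols(tr) <- mc
    pr <- windowProfile(tr)
    pr <- permutationThreshold(tr, pr, nPerm = 200L, bulkSize = 30L, seed = 3)
    regions <- callCandidateRegions(pr, track = tr)
    expect_gt(length(regions), 0)
    expect_true(all(GenomicRanges::start(regions) >= 1))
    expect_true(all(GenomicRanges::end(regions) <= 150000L))
    ## member markers are exactly those inside each region
    for (i in seq_along(regions)) {
        inR <- GenomicRanges::start(tr) >= GenomicRanges::start(regions)[i] &
            GenomicRanges::start(tr) <= GenomicRanges::end(regions)[i]
        expect_setequal(S4Vectors::mcols(regions)$markerIds[[i]],
                        names(tr)[inR])
    }
})

test_that("stronger QTL effects give larger peak windowed deltas on average", {
    peakFor <- function(effect, seed) {
        sim <- SimConfig(nMarkersPerChrom = 400L, chromLengthBp = 800000L,
                         qtlPosBp = 400000L, qtlEffect = effect, seed = seed)
        set.seed(seed)
        geno <- simulateF2Population(sim)
        h <- simulatePhenotypes(geno, sim)
        bulks <- selectBulks(h, k = sim@bulkSize)
        rec <- simulateBulkReads(geno, bulks, sim)
        tr <- filterMarkers(computeSnpIndex(callParentInformativeMarkers(rec)))
        pr <- windowProfile(tr)
        max(abs(S4Vectors::mcols(pr)$meanDelta), na.rm = TRUE)
    }
    seeds <- 301:304
    weak <- mean(vapply(seeds, function(s) peakFor(0, s), numeric(1)))
    mid <- mean(vapply(seeds, function(s) peakFor(-6, s), numeric(1)))
    strong <- mean(vapply(seeds, function(s) peakFor(-15, s), numeric(1)))
    expect_lt(weak, mid)
    expect_lt(mid, strong)
})
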