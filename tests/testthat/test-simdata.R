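test_that("fully linked markers segregate identically and empty populations work", {
    cfg <- SimConfig(nChromosomes = 1L, chromLengthBp = 10000L,
                     nMarkersPerChrom = 2L, popSize = 50L, bulkSize = 10L,
                     qtlPosBp = 5000L)
    mk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(5000L, 5000L),
                                                          width = 1L))
    geno <- simulateF2Population(cfg, markers = mk, seed = 1)
    d <- dosages(geno)
    expect_identical(d[, 1], d[, 2])

    cfg0 <- SimConfig(nChromosomes = 1L, chromLengthBp = 10000L,
                      nMarkersPerChrom = 2L, popSize = 0L, bulkSize = 0L,
                      qtlPosBp = 5000L)
    geno0 <- simulateF2Population(cfg0, markers = mk, seed = 1)
    expect_identical(nrow(dosages(geno0)), 0L)

    mkBad <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(6000L, 5000L),
                                                     width = 1L))
    expect_error(simulateF2Population(cfg, markers = mkBad, seed = 1),
                 "non-decreasing")
})

test_that("recombinant fraction follows Haldane's map function at 100 cM", {
    ## two markers 1 Mb apart at 100 cM/Mb = 1 Morgan
    r_expected <- (1 - exp(-2)) / 2
    cfg <- SimConfig(nChromosomes = 1L, chromLengthBp = 2000000L,
                     nMarkersPerChrom = 2L, recombRate = 100,
                     popSize = 10000L, bulkSize = 10L, qtlPosBp = 500000L)
    mk <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(500000L, 1500000L),
                                                  width = 1L))
    geno <- simulateF2Population(cfg, markers = mk, seed = 7)
    d <- dosages(geno)
    ## F2 dosage correlation between two loci is 1 - 2r
    r_hat <- (1 - cor(d[, 1], d[, 2])) / 2
    ## sampling sd of the correlation-based estimate
    rho <- 1 - 2 * r_expected
    sdR <- (1 - rho^2) / sqrt(nrow(d)) / 2
    expect_lt(abs(r_hat - r_expected), 3 * sdR)
})

test_that("phenotype model has the F2 additive variance and is reproducible", {
    cfg <- SimConfig(nChromosomes = 1L, chromLengthBp = 100000L,
                     nMarkersPerChrom = 5L, popSize = 10000L, bulkSize = 10L,
                     qtlPosBp = 50000L, qtlEffect = 12, envSd = 5)
    geno <- simulateF2Population(cfg, seed = 2)
    h <- simulatePhenotypes(geno, cfg, seed = 3)
    expected <- cfg@qtlEffect^2 / 2 + cfg@envSd^2
    expect_lt(abs(var(h) - expected) / expected, 0.05)

    h2 <- simulatePhenotypes(geno, cfg, seed = 3)
    expect_identical(h, h2)

    cfg0 <- SimConfig(qtlEffect = 0, envSd = 0)
    genoS <- simulateF2Population(
        SimConfig(nChromosomes = 1L, chromLengthBp = 1000L,
                  nMarkersPerChrom = 2L, popSize = 20L, bulkSize = 5L,
                  qtlPosBp = 500L, qtlEffect = 0, envSd = 0), seed = 1)
    hS <- simulatePhenotypes(
        genoS,
        SimConfig(nChromosomes = 1L, chromLengthBp = 1000L,
                  nMarkersPerChrom = 2L, popSize = 20L, bulkSize = 5L,
                  qtlPosBp = 500L, qtlEffect = 0, envSd = 0), seed = 1)
    expect_true(all(hS == hS[1]))   # baseline only
})

test_that("bulk read simulation follows the binomial error model", {
    cfg <- SimConfig(nChromosomes = 1L, chromLengthBp = 1000000L,
                     nMarkersPerChrom = 10000L, popSize = 20L,
                     bulkSize = 5L, qtlPosBp = 500000L, seqError = 0)
    geno <- simulateF2Population(cfg, seed = 4)
    ## force dwarf-allele frequency 0 in both bulks
    geno@dosage[] <- 0L
    bulks <- list(low = 1:5, high = 6:10)
    rec <- simulateBulkReads(geno, bulks, cfg, seed = 5)
    expect_true(all(S4Vectors::mcols(rec)$hbAlt == 0))
    expect_true(all(S4Vectors::mcols(rec)$lbAlt == 0))

    cfg0 <- SimConfig(nChromosomes = 1L, chromLengthBp = 1000000L,
                      nMarkersPerChrom = 100L, popSize = 20L, bulkSize = 5L,
                      qtlPosBp = 500000L, bulkDepthMean = 0)
    geno0 <- simulateF2Population(cfg0, seed = 4)
    rec0 <- simulateBulkReads(geno0, bulks, cfg0, seed = 5)
    expect_true(all(S4Vectors::mcols(rec0)$hbRef +
                    S4Vectors::mcols(rec0)$hbAlt == 0))

    ## p = 0.5 everywhere: mean alt fraction within 3 SE of 0.5
    geno@dosage[] <- 1L
    rec5 <- simulateBulkReads(geno, bulks, cfg, seed = 6)
    mc <- S4Vectors::mcols(rec5)
    frac <- sum(mc$hbAlt) / sum(mc$hbAlt + mc$hbRef)
    se <- 0.5 / sqrt(sum(mc$hbAlt + mc$hbRef))
    expect_lt(abs(frac - 0.5), 3 * se)

    expect_error(simulateBulkReads(geno, list(low = integer(), high = 1:5),
                                   cfg), "empty")
})

test_that("simulated gene models satisfy their construction invariants", {
    cfg <- SimConfig(nChromosomes = 2L, chromLengthBp = 200000L,
                     nMarkersPerChrom = 10L, popSize = 10L, bulkSize = 2L,
                     qtlPosBp = 100000L)
    gm <- simulateGeneModels(cfg, nGenesPerChrom = 8L, seed = 11)
    cds <- cdsRanges(gm$models)
    expect_true(all(sum(GenomicRanges::width(cds)) %% 3 == 0))
    genes <- geneRanges(gm$models)
    for (ch in unique(as.character(GenomicRanges::seqnames(genes)))) {
        g <- genes[GenomicRanges::seqnames(genes) == ch]
        expect_identical(
            length(GenomicRanges::reduce(g, min.gapwidth = 0L)), length(g))
    }
    expect_setequal(unique(as.character(GenomicRanges::strand(genes))),
                    c("+", "-"))
    ## every CDS starts with ATG in transcript orientation
    for (id in names(cds)) {
        seq <- bsaseq:::cdsSequence(cds[[id]], gm$genome)
        expect_identical(as.character(Biostrings::subseq(seq, 1, 3)), "ATG")
    }
})

test_that("gene models survive a GFF3 round trip", {
    cfg <- SimConfig(nChromosomes = 1L, chromLengthBp = 100000L,
                     nMarkersPerChrom = 10L, popSize = 10L, bulkSize = 2L,
                     qtlPosBp = 50000L)
    gm <- simulateGeneModels(cfg, nGenesPerChrom = 6L, seed = 12)
    path <- tempfile(fileext = ".gff3")
    writeGeneModels(gm$models, path)
    back <- readGeneModels(path)
    g0 <- geneRanges(gm$models)
    g1 <- geneRanges(back)
    o <- match(S4Vectors::mcols(g0)$geneId, S4Vectors::mcols(g1)$geneId)
    expect_false(anyNA(o))
    expect_identical(GenomicRanges::start(g1)[o], GenomicRanges::start(g0))
    expect_identical(GenomicRanges::end(g1)[o], GenomicRanges::end(g0))
    expect_identical(as.character(GenomicRanges::strand(g1)[o]),
                     as.character(GenomicRanges::strand(g0)))
    for (id in names(cdsRanges(gm$models))) {
        expect_identical(
            GenomicRanges::start(cdsRanges(back)[[id]]),
            GenomicRanges::start(cdsRanges(gm$models)[[id]]))
    }
})

test_that("RNA-seq counts follow the planted negative-binomial model", {
    ## Poisson limit: variance approximately equals the mean
    c0 <- simulateRnaseqCounts(paste0("g", 1:10000), dispersion = 0,
                               nReps = 1L, baseMeanRange = c(2, 2),
                               seed = 21)
    x <- c0[, "tall_1"]
    expect_lt(abs(var(x) / mean(x) - 1), 0.1)

    ## null symmetry: no planted genes, condition means agree
    cN <- simulateRnaseqCounts(paste0("g", 1:2000), dispersion = 0.05,
                               nReps = 3L, baseMeanRange = c(2, 2),
                               seed = 22)
    mT <- mean(cN[, 1:3]); mD <- mean(cN[, 4:6])
    expect_lt(abs(mT - mD) / mT, 0.05)

    ## planted 4-fold gene: mean ratio within 5% of 4 over many pairs
    plan <- data.frame(geneId = "g1", log2fc = 2)
    cs <- simulateRnaseqCounts(rep("g1", 1), plan, nReps = 1000L,
                               dispersion = 0.1, baseMeanRange = c(log10(500), log10(500)),
                               seed = 23)
    ratio <- mean(cs[1, 1001:2000]) / mean(cs[1, 1:1000])
    expect_lt(abs(ratio - 4) / 4, 0.05)

    expect_error(simulateRnaseqCounts("g1", dispersion = -1), "dispersion")
    expect_error(simulateRnaseqCounts("g1", nReps = 0L), "nReps")

    ## seeded bit-reproducibility
    a <- simulateRnaseqCounts(paste0("g", 1:50), seed = 31)
    b <- simulateRnaseqCounts(paste0("g", 1:50), seed = 31)
    expect_identical(a, b)
})
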