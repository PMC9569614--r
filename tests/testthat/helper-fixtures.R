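## shared fixture builders; everything is generated in code, no data files

## variant-record GRanges from a plain data.frame (chrom, pos, ref, alt,
## p1GT, p2GT, hbRef, hbAlt, lbRef, lbAlt); missing columns get defaults
makeVariants <- function(df) {
    defaults <- list(ref = "A", alt = "T", p1GT = "0/0", p2GT = "1/1",
                     hbRef = 10L, hbAlt = 10L, lbRef = 10L, lbAlt = 10L)
    for (nm in names(defaults))
        if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$pos, width = 1L))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        df[c("ref", "alt", "p1GT", "p2GT",
             "hbRef", "hbAlt", "lbRef", "lbAlt")])
    names(gr) <- sprintf("v%04d", seq_along(gr))
    gr
}

## random filtered-style track for window/threshold tests
makeRandomTrack <- function(n = 500, chromLen = 200000L, seed = 1,
                            nChrom = 1L) {
    set.seed(seed)
    chrom <- paste0("chr", sample.int(nChrom, n, replace = TRUE))
    pos <- unlist(lapply(split(seq_len(n), chrom), function(i)
        sort(sample.int(chromLen, length(i)))))
    chrom <- rep(names(split(seq_len(n), chrom)),
                 lengths(split(seq_len(n), chrom)))
    dH <- rpois(n, 50) + 7L
    dL <- rpois(n, 50) + 7L
    aH <- rbinom(n, dH, 0.5)
    aL <- rbinom(n, dL, 0.5)
    df <- data.frame(chrom = chrom, pos = pos,
                     hbRef = dH - aH, hbAlt = aH,
                     lbRef = dL - aL, lbAlt = aL)
    gr <- makeVariants(df)
    GenomeInfoDb::seqlengths(gr) <-
        setNames(rep(chromLen, length(unique(chrom))), unique(chrom))
    computeSnpIndex(gr)
}

## one-gene models on a tiny genome, for effect-classifier unit cases
makeTinyGene <- function(cdsSeq = "ATGGCTAAATAG", strand = "+",
                         flank = 20L, chrom = "chrT") {
    cdsLen <- nchar(cdsSeq)
    stopifnot(cdsLen %% 3 == 0)
    set.seed(99)
    left <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
    right <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
    insert <- if (strand == "+") cdsSeq
    else as.character(Biostrings::reverseComplement(Biostrings::DNAString(cdsSeq)))
    genome <- Biostrings::DNAStringSet(paste0(left, insert, right))
    names(genome) <- chrom
    cdsStart <- flank + 1L
    cdsEnd <- flank + cdsLen
    genes <- GenomicRanges::GRanges(chrom,
                                    IRanges::IRanges(max(1L, cdsStart - 10L),
                                                     cdsEnd + 10L),
                                    strand = strand)
    S4Vectors::mcols(genes)$geneId <- "g1"
    models <- new("GeneModels", genes = genes,
                  cds = GenomicRanges::GRangesList(
                      g1 = GenomicRanges::GRanges(
                          chrom, IRanges::IRanges(cdsStart, cdsEnd),
                          strand = strand)))
    list(models = models, genome = genome,
         cdsStart = cdsStart, cdsEnd = cdsEnd)
}

## independent effect oracle: substitute the base in the genome, re-extract
## and translate the WHOLE mutant CDS, and diff the protein
oracleClassify <- function(chrom, pos, alt, models, genome) {
    genes <- geneRanges(models)
    cdsL <- cdsRanges(models)
    hit <- which(as.character(GenomicRanges::seqnames(genes)) == chrom &
                 GenomicRanges::start(genes) <= pos &
                 GenomicRanges::end(genes) >= pos)
    if (!length(hit)) return("intergenic")
    for (gi in hit) {
        gid <- S4Vectors::mcols(genes)$geneId[gi]
        cds <- cdsL[[gid]]
        inCds <- any(GenomicRanges::start(cds) <= pos &
                     GenomicRanges::end(cds) >= pos)
        if (!inCds) next
        ch <- as.character(GenomicRanges::seqnames(genes)[gi])
        mutGenome <- genome
        Biostrings::subseq(mutGenome[[ch]], pos, pos) <-
            Biostrings::DNAString(alt)
        extract <- function(g) {
            segs <- sort(cds)
            s <- do.call(Biostrings::xscat,
                         lapply(seq_along(segs), function(i)
                             Biostrings::subseq(g[[ch]],
                                                GenomicRanges::start(segs)[i],
                                                GenomicRanges::end(segs)[i])))
            if (as.character(GenomicRanges::strand(cds)[1]) == "-")
                s <- Biostrings::reverseComplement(s)
            s
        }
        pRef <- as.character(Biostrings::translate(extract(genome),
                                                   if.fuzzy.codon = "X"))
        pAlt <- as.character(Biostrings::translate(extract(mutGenome),
                                                   if.fuzzy.codon = "X"))
        refAA <- strsplit(pRef, "")[[1]]
        altAA <- strsplit(pAlt, "")[[1]]
        changed <- which(refAA != altAA)
        if (!length(changed)) return("synonymous")
        return(if (refAA[changed] != "*" && altAA[changed] == "*") "stop-gain"
               else if (refAA[changed] == "*" && altAA[changed] != "*") "stop-loss"
               else "non-synonymous")
    }
    "intronic"
}
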