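VARIANT_TSV_COLS <- c("chrom", "pos", "ref", "alt", "p1_gt", "p2_gt",
                      "hb_ref", "hb_alt", "lb_ref", "lb_alt")

#' Write variant records as the bulked-segregant TSV dialect
#'
#' Plain tab-separated table with columns chrom, pos, ref, alt, p1_gt,
#' p2_gt, hb_ref, hb_alt, lb_ref, lb_alt (high-bulk / low-bulk reference
#' and alternate allele read counts), 1-based positions.
#'
#' @param records variant `GRanges` (see [simulateBulkReads()]).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeVariantTable <- function(records, path) {
    mc <- mcols(records)
    df <- data.frame(chrom = as.character(seqnames(records)),
                     pos = start(records),
                     ref = mc$ref, alt = mc$alt,
                     p1_gt = mc$p1GT, p2_gt = mc$p2GT,
                     hb_ref = mc$hbRef, hb_alt = mc$hbAlt,
                     lb_ref = mc$lbRef, lb_alt = mc$lbAlt)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read variant records (TSV dialect or VCF 4.2)
#'
#' The TSV dialect is the package's own interchange format (see
#' [writeVariantTable()]). VCF input must carry GT for the two parent
#' samples and AD (allelic depths) for the two bulk samples; only biallelic
#' SNVs are kept. Malformed TSV lines are reported with their line number.
#'
#' @param path input file.
#' @param dialect `"auto"` (by file extension), `"tsv"` or `"vcf"`.
#' @param samples for VCF input, a named list/character vector giving the
#'   sample names of `p1` (tall parent), `p2` (dwarf parent), `high` and
#'   `low` bulks.
#' @return variant `GRanges` with the metadata columns used throughout the
#'   package (`ref`, `alt`, `p1GT`, `p2GT`, `hbRef`, `hbAlt`, `lbRef`,
#'   `lbAlt`).
#' @export
readVariantTable <- function(path, dialect = c("auto", "tsv", "vcf"),
                             samples = NULL) {
    dialect <- match.arg(dialect)
    if (dialect == "auto")
        dialect <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
    if (dialect == "vcf")
        return(readVariantVcf(path, samples))
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character")
    if (nrow(df) == 0L) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(ref = character(), alt = character(),
                               p1GT = character(), p2GT = character(),
                               hbRef = integer(), hbAlt = integer(),
                               lbRef = integer(), lbAlt = integer())
        return(gr)
    }
    miss <- setdiff(VARIANT_TSV_COLS, colnames(df))
    if (length(miss))
        stop("variant table is missing column(s): ",
             paste(miss, collapse = ", "))
    intCols <- c("pos", "hb_ref", "hb_alt", "lb_ref", "lb_alt")
    for (cc in intCols) {
        v <- suppressWarnings(as.integer(df[[cc]]))
        bad <- which(is.na(v) & !is.na(df[[cc]]) | df[[cc]] == "")
        if (length(bad) || anyNA(v))
            stop("malformed value in column '", cc, "' at line ",
                 (if (length(bad)) bad[1] else which(is.na(v))[1]) + 1L,
                 " of ", path)
        df[[cc]] <- v
    }
    gr <- GRanges(df$chrom, IRanges(df$pos, width = 1L))
    mcols(gr) <- DataFrame(ref = df$ref, alt = df$alt,
                           p1GT = df$p1_gt, p2GT = df$p2_gt,
                           hbRef = df$hb_ref, hbAlt = df$hb_alt,
                           lbRef = df$lb_ref, lbAlt = df$lb_alt)
    names(gr) <- sprintf("m%05d", seq_along(gr))
    gr
}

readVariantVcf <- function(path, samples) {
    if (is.null(samples) ||
        !all(c("p1", "p2", "high", "low") %in% names(samples)))
        stop("VCF input needs samples = list(p1=, p2=, high=, low=)")
    vcf <- VariantAnnotation::readVcf(path)
    ## biallelic SNVs only
    keep <- lengths(VariantAnnotation::alt(vcf)) == 1L &
        width(VariantAnnotation::ref(vcf)) == 1L
    vcf <- vcf[keep]
    altChar <- as.character(unlist(VariantAnnotation::alt(vcf)))
    keep2 <- nchar(altChar) == 1L
    vcf <- vcf[keep2]
    altChar <- altChar[keep2]
    geno <- VariantAnnotation::geno(vcf)
    if (!"GT" %in% names(geno))
        stop("VCF lacks the GT field")
    if (!"AD" %in% names(geno))
        stop("VCF lacks the AD field needed for samples '",
             samples[["high"]], "' and '", samples[["low"]], "'")
    gt <- geno$GT
    ad <- geno$AD
    for (s in unlist(samples[c("p1", "p2", "high", "low")]))
        if (!s %in% colnames(gt))
            stop("sample '", s, "' not present in ", path)
    adOf <- function(s, slot) {
        vals <- ad[, samples[[s]]]
        if (any(vapply(vals, function(v) length(v) < 2L || anyNA(v),
                       logical(1))))
            stop("missing AD values for sample '", samples[[s]], "'")
        vapply(vals, `[`, numeric(1), slot)
    }
    normGT <- function(g) {
        g <- gsub("\\|", "/", g)
        g[g %in% c("1/0")] <- "0/1"
        g[!g %in% c("0/0", "0/1", "1/1")] <- "./."
        g
    }
    rr <- SummarizedExperiment::rowRanges(vcf)
    gr <- GRanges(seqnames(rr), IRanges(start(rr), width = 1L))
    mcols(gr) <- DataFrame(
        ref = as.character(VariantAnnotation::ref(vcf)),
        alt = altChar,
        p1GT = unname(normGT(gt[, samples[["p1"]]])),
        p2GT = unname(normGT(gt[, samples[["p2"]]])),
        hbRef = as.integer(adOf("high", 1L)),
        hbAlt = as.integer(adOf("high", 2L)),
        lbRef = as.integer(adOf("low", 1L)),
        lbAlt = as.integer(adOf("low", 2L)))
    names(gr) <- rownames(vcf) %||% sprintf("m%05d", seq_along(gr))
    gr
}

#' Write gene models to GFF3 (with gene/mRNA/CDS features)
#'
#' @param models a [GeneModels].
#' @param path output GFF3 file.
#' @return invisibly, `path`.
#' @export
writeGeneModels <- function(models, path) {
    stopifnot(is(models, "GeneModels"))
    genes <- geneRanges(models)
    cds <- cdsRanges(models)
    ids <- mcols(genes)$geneId
    rows <- GRanges()
    feats <- list()
    for (i in seq_along(genes)) {
        id <- ids[i]
        g <- granges(genes[i])
        mrna <- g
        segs <- sort(cds[[id]])   # GFF3 stores ascending coordinates
        n <- length(segs)
        featGr <- c(g, mrna, granges(segs))
        mcols(featGr)$type <- c("gene", "mRNA", rep("CDS", n))
        mcols(featGr)$ID <- c(id, paste0(id, ".t1"),
                              paste0(id, ".t1.cds", seq_len(n)))
        mcols(featGr)$Parent <- IRanges::CharacterList(
            c(list(character(0)), list(id),
              rep(list(paste0(id, ".t1")), n)))
        mcols(featGr)$phase <- c(NA_integer_, NA_integer_,
                                 gffPhases(segs, strand = as.character(strand(g))))
        feats[[i]] <- featGr
    }
    all <- do.call(c, feats)
    mcols(all)$source <- "bsaseq"
    rtracklayer::export(all, path, format = "gff3")
    invisible(path)
}

## GFF3 phase column for CDS segments sorted in ascending coordinates
gffPhases <- function(segsAsc, strand) {
    w <- width(segsAsc)
    if (strand == "-") w <- rev(w)
    phases <- cumsum(c(0L, w[-length(w)])) %% 3L
    phases <- (3L - phases) %% 3L
    if (strand == "-") phases <- rev(phases)
    phases
}

#' Read gene models from GFF3
#'
#' Accepts gene/mRNA/CDS features; CDS segments are grouped through their
#' Parent chain, ordered 5' to 3' after load (decreasing coordinates on the
#' minus strand) and, when a gene has several isoforms, the longest CDS is
#' kept. A gene whose CDS length is not divisible by 3 is an error naming
#' the gene.
#'
#' @param path GFF3 file.
#' @return a [GeneModels].
#' @export
readGeneModels <- function(path) {
    gff <- rtracklayer::import(path, format = "gff3")
    if (length(gff) == 0L)
        return(new("GeneModels", genes = GRanges(geneId = character()),
                   cds = GRangesList()))
    type <- as.character(mcols(gff)$type)
    genes <- gff[type == "gene"]
    mrnas <- gff[type == "mRNA"]
    cdss <- gff[type == "CDS"]
    firstParent <- function(x) vapply(as.list(mcols(x)$Parent),
                                      function(p) p[1] %||% NA_character_,
                                      character(1))
    mrnaGene <- setNames(firstParent(mrnas), mcols(mrnas)$ID)
    cdsTx <- firstParent(cdss)
    byTx <- split(seq_along(cdss), cdsTx)
    ## longest CDS per gene
    txLen <- vapply(byTx, function(i) sum(width(cdss[i])), numeric(1))
    txGene <- mrnaGene[names(byTx)]
    bestTx <- vapply(split(names(byTx), txGene),
                     function(txs) txs[which.max(txLen[txs])], character(1))
    cdsList <- list()
    for (g in names(bestTx)) {
        segs <- cdss[byTx[[bestTx[[g]]]]]
        segs <- sort(segs)
        if (as.character(strand(segs)[1]) == "-")
            segs <- rev(segs)           # 5'->3' on minus strand
        total <- sum(width(segs))
        if (total %% 3L != 0L)
            stop("CDS length of gene '", g, "' (", total,
                 " bp) is not divisible by 3")
        cdsList[[g]] <- granges(segs)
    }
    geneGr <- granges(genes)
    mcols(geneGr)$geneId <- as.character(mcols(genes)$ID)
    geneGr <- geneGr[mcols(geneGr)$geneId %in% names(cdsList)]
    new("GeneModels", genes = geneGr, cds = GRangesList(cdsList))
}

#' Write candidate regions as BED
#'
#' BED uses 0-based half-open coordinates; the 1-based inclusive regions
#' are converted on the way out.
#'
#' @param regions `GRanges` of candidate regions (1-based inclusive).
#' @param path output BED file.
#' @return invisibly, `path`.
#' @export
writeRegionsBed <- function(regions, path) {
    df <- data.frame(chrom = as.character(seqnames(regions)),
                     start = start(regions) - 1L,   # 0-based half-open
                     end = end(regions),
                     name = sprintf("region%02d", seq_along(regions)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Convert between 1-based inclusive and 0-based half-open intervals
#'
#' `toBed()` maps 1-based inclusive (VCF/GFF) starts/ends to BED
#' conventions; `fromBed()` inverts it.
#'
#' @param start,end interval bounds.
#' @return two-column `data.frame` of converted bounds.
#' @export
toBed <- function(start, end) data.frame(start = start - 1L, end = end)

#' @rdname toBed
#' @export
fromBed <- function(start, end) data.frame(start = start + 1L, end = end)
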