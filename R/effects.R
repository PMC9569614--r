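EFFECT_LEVELS <- c("intergenic", "intronic", "synonymous",
                   "non-synonymous", "stop-gain", "stop-loss")

## 0-based offset within the CDS of a genomic position, honouring strand.
## cds: GRanges segments ordered 5'->3'. Returns NA when pos not in the CDS.
cdsOffset <- function(pos, cds) {
    widths <- width(cds)
    before <- c(0L, cumsum(widths))[seq_along(widths)]
    minus <- as.character(strand(cds)[1]) == "-"
    for (i in seq_along(cds)) {
        if (pos >= start(cds)[i] && pos <= end(cds)[i]) {
            within <- if (minus) end(cds)[i] - pos else pos - start(cds)[i]
            return(before[i] + within)
        }
    }
    NA_integer_
}

## spliced CDS sequence, 5'->3'
cdsSequence <- function(cds, genome) {
    ch <- as.character(seqnames(cds)[1])
    segs <- lapply(seq_along(cds), function(i)
        Biostrings::subseq(genome[[ch]], start(cds)[i], end(cds)[i]))
    minus <- as.character(strand(cds)[1]) == "-"
    if (minus) segs <- rev(segs)   # stored 5'->3' = decreasing coords on minus
    s <- do.call(Biostrings::xscat, segs)
    if (minus) Biostrings::reverseComplement(s) else s
}

#' Classify single-nucleotide variants against gene models
#'
#' Each SNV is located against the gene models: outside every gene span it
#' is `intergenic`; inside a gene but outside its CDS it is `intronic`
#' (gene-body, covering introns and UTRs); inside the CDS the affected
#' codon is substituted (alleles reverse-complemented on the minus strand)
#' and translated with the standard genetic code, giving `synonymous`
#' (same amino acid), `non-synonymous` (different, neither a stop),
#' `stop-gain` (non-stop to stop) or `stop-loss` (stop to non-stop); the
#' stop classes take precedence by construction. A variant whose reference
#' allele disagrees with the genome sequence raises an error, which catches
#' coordinate or strand bookkeeping bugs early.
#'
#' A variant overlapping several genes is classified against the first
#' containing gene with a CDS hit, preferring coding over gene-body
#' context.
#'
#' @param variants `GRanges` of SNVs with metadata columns `ref` and `alt`
#'   (single bases, plus-strand alleles).
#' @param models a [GeneModels].
#' @param genome `DNAStringSet` named by chromosome.
#' @return `data.frame` with `variantId`, `geneId` (`NA` outside genes) and
#'   `effect` (factor with levels intergenic, intronic, synonymous,
#'   non-synonymous, stop-gain, stop-loss).
#' @export
classifyVariants <- function(variants, models, genome) {
    stopifnot(is(models, "GeneModels"))
    mc <- mcols(variants)
    if (is.null(mc$ref) || is.null(mc$alt))
        stop("variants must carry ref and alt metadata columns")
    ids <- names(variants) %||% as.character(seq_along(variants))
    genes <- geneRanges(models)
    cds <- cdsRanges(models)
    geneIds <- mcols(genes)$geneId
    cdsSeqCache <- new.env(parent = emptyenv())
    getCdsSeq <- function(id) {
        if (is.null(cdsSeqCache[[id]]))
            cdsSeqCache[[id]] <- cdsSequence(cds[[id]], genome)
        cdsSeqCache[[id]]
    }
    hits <- findOverlaps(variants, genes, ignore.strand = TRUE)
    hitList <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
    effect <- rep("intergenic", length(variants))
    outGene <- rep(NA_character_, length(variants))
    code <- Biostrings::GENETIC_CODE
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    for (vi in as.integer(names(hitList))) {
        pos <- start(variants)[vi]
        ch <- as.character(seqnames(variants))[vi]
        refAllele <- toupper(mc$ref[vi])
        altAllele <- toupper(mc$alt[vi])
        genomeBase <- as.character(Biostrings::subseq(genome[[ch]], pos, pos))
        if (genomeBase != refAllele)
            stop("reference allele mismatch at ", ch, ":", pos,
                 " (variant ", ids[vi], ": ref ", refAllele,
                 ", genome ", genomeBase, ")")
        call <- NULL
        for (gi in hitList[[as.character(vi)]]) {
            gid <- geneIds[gi]
            off <- cdsOffset(pos, cds[[gid]])
            if (is.na(off)) {
                if (is.null(call)) call <- list(gene = gid, eff = "intronic")
                next
            }
            minus <- as.character(strand(cds[[gid]])[1]) == "-"
            cdsSeq <- getCdsSeq(gid)
            codonIdx <- off %/% 3L
            within <- off %% 3L
            codon <- as.character(Biostrings::subseq(cdsSeq,
                                                     codonIdx * 3L + 1L,
                                                     codonIdx * 3L + 3L))
            altCds <- if (minus) comp[[altAllele]] else altAllele
            mutant <- codon
            substr(mutant, within + 1L, within + 1L) <- altCds
            aaRef <- code[[codon]]
            aaAlt <- code[[mutant]]
            eff <- if (aaRef == aaAlt) "synonymous"
            else if (aaRef != "*" && aaAlt == "*") "stop-gain"
            else if (aaRef == "*" && aaAlt != "*") "stop-loss"
            else "non-synonymous"
            call <- list(gene = gid, eff = eff)
            break   # coding context wins over gene-body context
        }
        effect[vi] <- call$eff
        outGene[vi] <- call$gene
    }
    data.frame(variantId = ids, geneId = outGene,
               effect = factor(effect, levels = EFFECT_LEVELS))
}

#' Genes with protein-altering variants inside candidate regions
#'
#' Selects variants lying inside any candidate region whose effect class is
#' protein-altering (non-synonymous, stop-gain or stop-loss) and counts
#' them per gene.
#'
#' @param effects `data.frame` from [classifyVariants()].
#' @param regions `GRanges` of candidate regions.
#' @param variants the `GRanges` the effects were computed from (provides
#'   positions; names must match `effects$variantId`).
#' @return `data.frame` with `geneId` and `nSites`, one row per gene with
#'   at least one qualifying site, sorted by decreasing `nSites`.
#' @export
genesWithNonsynInRegions <- function(effects, regions, variants) {
    ids <- names(variants) %||% as.character(seq_along(variants))
    stopifnot(all(effects$variantId %in% ids))
    vr <- variants[match(effects$variantId, ids)]
    inRegion <- countOverlaps(vr, regions, ignore.strand = TRUE) > 0
    altering <- effects$effect %in% c("non-synonymous", "stop-gain", "stop-loss")
    sel <- effects[inRegion & altering & !is.na(effects$geneId), , drop = FALSE]
    if (!nrow(sel))
        return(data.frame(geneId = character(), nSites = integer()))
    tab <- sort(table(sel$geneId), decreasing = TRUE)
    data.frame(geneId = names(tab), nSites = as.integer(tab),
               row.names = NULL)
}
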