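#' Keep only parent-informative markers
#'
#' A marker is informative for bulked segregant analysis when both parents
#' are homozygous for different alleles; heterozygous or missing parent
#' genotypes, and loci where the parents agree, are dropped (records are
#' never mutated).
#'
#' @param records `GRanges` of variant records as produced by
#'   [simulateBulkReads()] or [readVariantTable()] (metadata columns
#'   `p1GT`, `p2GT` with values `"0/0"`, `"1/1"`, `"0/1"`, `"./."`).
#' @return the informative subset of `records`.
#' @export
callParentInformativeMarkers <- function(records) {
    gt1 <- mcols(records)$p1GT
    gt2 <- mcols(records)$p2GT
    if (is.null(gt1) || is.null(gt2))
        stop("records must carry p1GT and p2GT metadata columns")
    hom <- c("0/0", "1/1")
    keep <- gt1 %in% hom & gt2 %in% hom & gt1 != gt2
    records[keep]
}

#' Compute the per-bulk SNP-index
#'
#' The SNP-index of a bulk at a marker is the fraction of its reads that
#' carry the dwarf-parent (P2) allele, so a bulk identical to the tall
#' reference parent has index 0 and a bulk identical to the dwarf parent
#' has index 1. Computed from allele read counts, never from called
#' genotypes; missing (`NA`) where the bulk has zero depth.
#' `delta = indexHigh - indexLow` is present only when both indices are.
#'
#' @param records informative variant records
#'   (see [callParentInformativeMarkers()]).
#' @param orientTo which parent's allele frequency the index measures;
#'   `"P2"` (dwarf, the default) or `"P1"`. Reorienting maps every index to
#'   `1 - index` and delta to `-delta`.
#' @return a [SnpIndexTrack].
#' @export
computeSnpIndex <- function(records, orientTo = c("P2", "P1")) {
    orientTo <- match.arg(orientTo)
    mc <- mcols(records)
    need <- c("p1GT", "p2GT", "hbRef", "hbAlt", "lbRef", "lbAlt")
    if (!all(need %in% colnames(mc)))
        stop("records must carry columns: ", paste(need, collapse = ", "))
    ## allele carried by the orientation parent: P2 hom-alt -> alt, etc.
    gt <- if (orientTo == "P2") mc$p2GT else mc$p1GT
    if (!all(gt %in% c("0/0", "1/1")))
        stop("orientation parent must be homozygous at every marker; ",
             "run callParentInformativeMarkers() first")
    isAlt <- gt == "1/1"
    dwarfHigh <- ifelse(isAlt, mc$hbAlt, mc$hbRef)
    dwarfLow <- ifelse(isAlt, mc$lbAlt, mc$lbRef)
    depthHigh <- mc$hbRef + mc$hbAlt
    depthLow <- mc$lbRef + mc$lbAlt
    indexHigh <- ifelse(depthHigh > 0, dwarfHigh / depthHigh, NA_real_)
    indexLow <- ifelse(depthLow > 0, dwarfLow / depthLow, NA_real_)
    gr <- GRanges(seqnames(records), IRanges(start(records), width = 1L))
    seqlengths(gr) <- seqlengths(records)
    names(gr) <- names(records)
    mcols(gr) <- DataFrame(
        dwarfAllele = ifelse(isAlt, mc$alt, mc$ref),
        dwarfHigh = dwarfHigh, dwarfLow = dwarfLow,
        depthHigh = depthHigh, depthLow = depthLow,
        indexHigh = indexHigh, indexLow = indexLow,
        delta = indexHigh - indexLow)
    out <- new("SnpIndexTrack", gr)
    metadata(out)$orientation <- paste0(orientTo, "-allele frequency")
    out
}

#' Filter SNP-index markers by index and depth
#'
#' Drops a locus when (a) its SNP-index is below `indexMin` in both bulks
#' (a locus with no allele-frequency signal anywhere), or (b) its depth is
#' below `depthMin` (by default in either bulk: a shallow bulk makes its
#' index unreliable regardless of the other; set `depthRule = "both"` for
#' the laxer reading), or (c) its index is missing in any bulk. Boundaries
#' are inclusive: a locus at exactly `indexMin` or `depthMin` is retained.
#' The filter is idempotent.
#'
#' @param track a [SnpIndexTrack].
#' @param indexMin minimum SNP-index (default 0.3).
#' @param depthMin minimum bulk depth in reads (default 7).
#' @param depthRule `"either"` (default) drops the locus when either bulk
#'   is shallow; `"both"` only when both are.
#' @return the filtered [SnpIndexTrack].
#' @export
filterMarkers <- function(track, indexMin = 0.3, depthMin = 7,
                          depthRule = c("either", "both")) {
    depthRule <- match.arg(depthRule)
    stopifnot(is(track, "SnpIndexTrack"))
    mc <- mcols(track)
    missingAny <- is.na(mc$indexHigh) | is.na(mc$indexLow)
    lowIndexBoth <- !missingAny & mc$indexHigh < indexMin & mc$indexLow < indexMin
    lowDepth <- if (depthRule == "either")
        mc$depthHigh < depthMin | mc$depthLow < depthMin
    else
        mc$depthHigh < depthMin & mc$depthLow < depthMin
    keep <- !(missingAny | lowIndexBoth | lowDepth)
    out <- track[keep]
    metadata(out)$filter <- list(indexMin = indexMin, depthMin = depthMin,
                                 depthRule = depthRule)
    out
}
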