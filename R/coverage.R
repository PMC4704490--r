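#' Exonic coverage profile of one gene
#'
#' Per-base read depth over a gene's exonic span (intronic positions are
#' excluded). `pos` holds the genomic coordinates of the exonic bases in
#' ascending order and `depth` the number of alignment blocks covering each.
#'
#' @slot gene gene id.
#' @slot pos integer vector of exonic genomic positions.
#' @slot depth integer vector, same length as `pos`.
#' @slot nIgnored number of alignment blocks that fell entirely outside the
#'   gene span and were ignored.
#' @export
setClass("CoverageProfile", representation(
    gene = "character", pos = "integer", depth = "integer", nIgnored = "integer"))

#' @describeIn CoverageProfile-class compact display.
#' @param object a `CoverageProfile`.
#' @export
setMethod("show", "CoverageProfile", function(object) {
    cat(sprintf("CoverageProfile for %s: %d exonic bases, %.1f%% covered, max depth %d\n",
                object@gene, length(object@pos),
                100 * mean(object@depth > 0),
                if (length(object@depth)) max(object@depth) else 0L))
    invisible(object)
})

#' Compute a gene's exonic coverage profile
#'
#' Depth at each exonic base is the number of alignment blocks (of reads
#' assigned to `gene`) covering it. Blocks entirely outside the gene span are
#' ignored with a message; blocks overlapping introns contribute only where
#' they overlap exons.
#'
#' @param readSet a [ReadSet-class] (reads of one cell).
#' @param genes a [GeneModelSet-class].
#' @param gene gene id.
#' @return a [CoverageProfile-class].
#' @export
computeCoverage <- function(readSet, genes, gene) {
    exIr <- ranges(exonRanges(genes, gene))
    sel <- readSet@reads$gene_id == gene
    bl <- unlist(readSet@reads$blocks[sel], use.names = FALSE)
    spanLo <- min(start(exIr)); spanHi <- max(end(exIr))
    outside <- end(bl) < spanLo | start(bl) > spanHi
    if (any(outside))
        message(sum(outside), " block(s) outside the span of ", gene, " ignored")
    bl <- bl[!outside]
    pos <- as.integer(unlist(Map(seq.int, start(exIr), end(exIr))))
    # work in gene-local coordinates so the coverage vector stays small
    blLoc <- IRanges(pmax(start(bl) - spanLo + 1L, 1L),
                     pmin(end(bl), spanHi) - spanLo + 1L)
    cvg <- as.integer(coverage(blLoc, width = spanHi - spanLo + 1L))
    new("CoverageProfile", gene = gene, pos = pos,
        depth = cvg[pos - spanLo + 1L], nIgnored = sum(outside))
}

#' Criterion (i): is the coding sequence completely covered?
#'
#' TRUE iff every CDS base has depth >= 1 in the profile. A truncated,
#' non-coding transcript leaves part of the CDS uncovered and fails.
#'
#' @param profile a [CoverageProfile-class].
#' @param genes a [GeneModelSet-class].
#' @param gene gene id (default: the profile's gene).
#' @return logical scalar.
#' @export
checkCdsCoverage <- function(profile, genes, gene = profile@gene) {
    cds <- ranges(cdsRanges(genes, gene))
    if (length(cds) == 0L)
        stop(gene, " has an empty CDS; receptor genes must have a CDS")
    cdsPos <- as.integer(unlist(Map(seq.int, start(cds), end(cds))))
    d <- profile@depth[match(cdsPos, profile@pos)]
    if (anyNA(d)) stop("profile does not cover the CDS positions of ", gene)
    all(d >= 1L)
}

#' Criterion (ii): do enough reads have high mapping quality?
#'
#' A mismapped homolog sheds reads of low mapping quality; a truly expressed
#' receptor has a large high-MAPQ fraction (> 80% in most cells).
#'
#' @param mapq integer vector of per-read MAPQ values for the gene (or a
#'   [ReadSet-class] together with `gene`).
#' @param mapqMin MAPQ at or above which a read counts as high quality
#'   (default 30).
#' @param fracMin minimum high-quality fraction (default 0.8).
#' @param gene gene id, when `mapq` is a `ReadSet`.
#' @return list with `fraction` (0 when there are no reads) and `ok`.
#' @export
checkMapq <- function(mapq, mapqMin = 30, fracMin = 0.8, gene = NULL) {
    if (is(mapq, "ReadSet")) {
        stopifnot(!is.null(gene))
        mapq <- mapq@reads$mapq[mapq@reads$gene_id == gene]
    }
    if (length(mapq) == 0L) return(list(fraction = 0, ok = FALSE))
    frac <- mean(mapq >= mapqMin)
    list(fraction = frac, ok = frac >= fracMin)
}

# annotated introns of a gene (possibly empty)
.intronRanges <- function(genes, gene) {
    ex <- ranges(exonRanges(genes, gene))
    if (length(ex) < 2L) return(IRanges())
    IRanges(end(ex)[-length(ex)] + 1L, start(ex)[-1L] - 1L)
}

#' Criterion (iii): do some reads span an annotated intron?
#'
#' TRUE iff at least one read assigned to the gene has >= 2 blocks and one of
#' its gaps coincides *exactly* with an annotated intron (both endpoints;
#' tolerance 0). Reads whose gaps do not match an annotated intron provide no
#' splice evidence; a read set with none is consistent with genomic-DNA
#' contamination.
#'
#' @param readSet a [ReadSet-class].
#' @param genes a [GeneModelSet-class].
#' @param gene gene id.
#' @return logical scalar.
#' @export
checkSpliced <- function(readSet, genes, gene) {
    introns <- .intronRanges(genes, gene)
    if (length(introns) == 0L) return(FALSE)
    bl <- readSet@reads$blocks[readSet@reads$gene_id == gene]
    bl <- bl[lengths(bl) >= 2L]
    for (b in as.list(bl)) {
        gs <- end(b)[-length(b)] + 1L
        ge <- start(b)[-1L] - 1L
        if (any(gs %in% start(introns) & ge %in% end(introns) &
                match(gs, start(introns)) == match(ge, end(introns))))
            return(TRUE)
    }
    FALSE
}

# fraction of UTR (exonic non-CDS) bases covered, for the optional rescue
.utrBreadth <- function(profile, genes, gene = profile@gene) {
    cds <- ranges(cdsRanges(genes, gene))
    cdsPos <- if (length(cds))
        as.integer(unlist(Map(seq.int, start(cds), end(cds)))) else integer()
    utr <- !(profile@pos %in% cdsPos)
    if (!any(utr)) return(0)
    mean(profile@depth[utr] > 0L)
}
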