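#' Gene models for the synthetic olfactory transcriptome
#'
#' `GeneModelSet` stores, per gene, the exon and CDS intervals (as
#' `GRangesList` objects named by gene id) plus a gene-level annotation table
#' with biotype (`OR`, `VR`, `TAAR`, `marker`, `housekeeping`, `smallRNA`),
#' homolog group and marker class. Receptor genes always carry at least two
#' exons — a spliced upstream exon preceding the CDS-bearing exon — so that
#' spliced-read evidence (criterion iii of the caller) is attainable, and a
#' non-empty CDS contained in the exon union (criterion i).
#'
#' @slot exons `GRangesList`, exons per gene (sorted, disjoint).
#' @slot cds `GRangesList`, CDS intervals per gene (possibly empty).
#' @slot geneData `DataFrame` with columns `chrom`, `strand`, `biotype`,
#'   `homologGroup` (NA outside receptor families) and `markerClass`
#'   (`none` outside markers); rownames are gene ids.
#' @export
setClass("GeneModelSet", representation(
    exons = "CompressedGRangesList",
    cds = "CompressedGRangesList",
    geneData = "DFrame"
))

setValidity("GeneModelSet", function(object) {
    msg <- character()
    ids <- rownames(object@geneData)
    if (!identical(names(object@exons), ids) || !identical(names(object@cds), ids))
        msg <- c(msg, "exons and cds must be named identically to geneData rownames")
    # sorted, pairwise-disjoint exons (vectorized over the unlisted ranges)
    exu <- unlist(object@exons, use.names = FALSE)
    grp <- rep(seq_along(object@exons), lengths(object@exons))
    if (length(exu) > 1L) {
        within <- grp[-1] == grp[-length(grp)]
        bad <- within & start(exu)[-1] <= end(exu)[-length(exu)]
        if (any(bad))
            msg <- c(msg, "exons must be sorted by start and pairwise disjoint within each gene")
    }
    # every CDS interval inside an exon of the same gene (exons are disjoint,
    # so union containment == containment in a single exon)
    cdu <- unlist(object@cds, use.names = FALSE)
    if (length(cdu)) {
        cdGene <- rep(seq_along(object@cds), lengths(object@cds))
        hits <- GenomicRanges::findOverlaps(cdu, exu, type = "within")
        okHit <- cdGene[S4Vectors::queryHits(hits)] == grp[S4Vectors::subjectHits(hits)]
        if (!all(seq_along(cdu) %in% S4Vectors::queryHits(hits)[okHit]))
            msg <- c(msg, "every CDS interval must lie within the gene's exon union")
    }
    bt <- object@geneData$biotype
    rec <- bt %in% .RECEPTOR_BIOTYPES
    if (any(rec & lengths(object@exons) < 2L))
        msg <- c(msg, "receptor genes must have >= 2 exons")
    if (any(rec & lengths(object@cds) == 0L))
        msg <- c(msg, "receptor genes must have a CDS")
    if (length(msg)) msg else TRUE
})

#' @describeIn GeneModelSet-class number of genes.
#' @param x a `GeneModelSet`.
#' @export
setMethod("length", "GeneModelSet", function(x) nrow(x@geneData))

#' @describeIn GeneModelSet-class gene identifiers.
#' @export
setMethod("geneIds", "GeneModelSet", function(x) rownames(x@geneData))

#' @describeIn GeneModelSet-class named biotype vector.
#' @export
setMethod("geneBiotype", "GeneModelSet", function(x)
    setNames(x@geneData$biotype, rownames(x@geneData)))

#' @describeIn GeneModelSet-class named marker-class vector.
#' @export
setMethod("markerClass", "GeneModelSet", function(x)
    setNames(x@geneData$markerClass, rownames(x@geneData)))

#' @describeIn GeneModelSet-class named homolog-group vector (NA outside
#'   receptor families).
#' @export
setMethod("homologGroup", "GeneModelSet", function(x)
    setNames(x@geneData$homologGroup, rownames(x@geneData)))

#' @describeIn GeneModelSet-class exon `GRangesList` (optionally for one gene).
#' @param gene optional single gene id.
#' @export
setMethod("exonRanges", "GeneModelSet", function(x, gene = NULL)
    if (is.null(gene)) x@exons else x@exons[[gene]])

#' @describeIn GeneModelSet-class CDS `GRangesList` (optionally for one gene).
#' @export
setMethod("cdsRanges", "GeneModelSet", function(x, gene = NULL)
    if (is.null(gene)) x@cds else x@cds[[gene]])

#' @describeIn GeneModelSet-class subset by gene ids or indices.
#' @param i gene ids or indices.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "GeneModelSet", function(x, i, j, ..., drop = FALSE)
    new("GeneModelSet", exons = x@exons[i], cds = x@cds[i],
        geneData = x@geneData[i, , drop = FALSE]))

#' @describeIn GeneModelSet-class compact display.
#' @param object a `GeneModelSet`.
#' @export
setMethod("show", "GeneModelSet", function(object) {
    tab <- table(object@geneData$biotype)
    cat("GeneModelSet with", length(object), "genes:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    invisible(object)
})

# Receptor gene ids (OR/VR/TAAR) of a set.
.receptorIds <- function(genes)
    rownames(genes@geneData)[genes@geneData$biotype %in% .RECEPTOR_BIOTYPES]

# The 44 default marker genes, by expression-pattern class. Names follow the
# standard olfactory-epithelium markers (Gap43/Gng8/Stmn1 for immature,
# Omp/Gng13/Stoml3 for mature, Neurog1/Ascl1 for precursors); identities only
# label the simulation, expression patterns come from markerClassCounts.
.DEFAULT_MARKERS <- list(
    immature_only = c("Gap43", "Gng8", "Stmn1", "Stmn2", "Stmn3", "Dpysl2",
                      "Dpysl3", "Dpysl5", "Hdac2", "Tubb3", "Sox11", "Elavl4",
                      "Crabp1"),
    both = c("Gnas", "Emx2", "Lhx2", "Ncam1", "Ebf1", "Ebf2", "Ebf3", "Omp2l"),
    mature_only = c("Omp", "Gng13", "Stoml3", "Cnga2", "Cnga4", "Cngb1",
                    "Adcy3", "Gnal", "Stmn4", "S100a5", "Car2", "Nqo1",
                    "Cyp2a4", "Ldhb", "Acsm4", "Dcx2l"),
    precursor_only = c("Neurog1", "Ascl1", "Neurod1", "Sox2", "Hes1", "Kit",
                       "Mki67")
)

#' Generate synthetic gene models
#'
#' Lays out a synthetic genome with `nOrGenes` OR genes (plus VR and TAAR
#' genes treated identically by the caller), `nMarkerGenes` developmental
#' markers partitioned into the four expression-pattern classes,
#' `nHousekeeping` background genes and at least 3 small-RNA genes. Every
#' receptor gene gets a short non-coding upstream exon, an intron of 1-4 kb
#' and a CDS-bearing exon with UTRs, and is assigned to a homolog group of
#' size >= 2 (the substrate for mismapping decoys). Genes are placed
#' non-overlapping along chromosomes chr1..chr10 with random intergenic gaps.
#' Deterministic given `config@seed`.
#'
#' @param config an [OrSimConfig-class].
#' @return a [GeneModelSet-class].
#' @examples
#' genes <- generateGeneModels(orSimConfig(seed = 1, nOrGenes = 10))
#' genes
#' @export
generateGeneModels <- function(config) {
    stopifnot(is(config, "OrSimConfig"))
    validObject(config)
    if (config@nOrGenes < 2L)
        stop("nOrGenes must be >= 2: homolog groups of size >= 2 are impossible otherwise")
    set.seed(config@seed)

    nOr <- config@nOrGenes; nVr <- config@nVrGenes; nTaar <- config@nTaarGenes
    ids <- c(sprintf("Olfr%04d", seq_len(nOr)),
             if (nVr) sprintf("Vmn1r%02d", seq_len(nVr)),
             if (nTaar) sprintf("Taar%02d", seq_len(nTaar)))
    biotype <- c(rep("OR", nOr), rep("VR", nVr), rep("TAAR", nTaar))

    # homolog groups of size 2-3 within each receptor family
    grpOf <- function(n, prefix) {
        if (n == 0L) return(character())
        sizes <- integer()
        while (sum(sizes) < n - 1L) sizes <- c(sizes, sample(2:3, 1L))
        if (sum(sizes) > n) sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
        if (sum(sizes) < n) sizes[length(sizes)] <- sizes[length(sizes)] + (n - sum(sizes))
        if (sizes[length(sizes)] < 2L && length(sizes) > 1L) {
            sizes[length(sizes) - 1L] <- sizes[length(sizes) - 1L] + sizes[length(sizes)]
            sizes <- sizes[-length(sizes)]
        }
        rep(sprintf("%s%03d", prefix, seq_along(sizes)), sizes)
    }
    homolog <- c(grpOf(nOr, "ORHG"), grpOf(nVr, "VRHG"), grpOf(nTaar, "TAARHG"))

    mk <- config@markerClassCounts
    markerIds <- character(0); markerCls <- character(0)
    for (cl in .MARKER_CLASSES) {
        pool <- .DEFAULT_MARKERS[[cl]]
        n <- mk[[cl]]
        nm <- if (n <= length(pool)) pool[seq_len(n)] else
            c(pool, sprintf("%s_x%02d", substr(cl, 1, 3), seq_len(n - length(pool))))
        markerIds <- c(markerIds, nm)
        markerCls <- c(markerCls, rep(cl, n))
    }
    hkIds <- sprintf("Hk%05d", seq_len(config@nHousekeeping))
    srIds <- sprintf("sRNA%02d", seq_len(config@nSmallRna))

    ids <- c(ids, markerIds, hkIds, srIds)
    biotype <- c(biotype, rep("marker", length(markerIds)),
                 rep("housekeeping", length(hkIds)), rep("smallRNA", length(srIds)))
    homolog <- c(homolog, rep(NA_character_, length(markerIds) + length(hkIds) + length(srIds)))
    markerClass <- c(rep("none", nOr + nVr + nTaar), markerCls,
                     rep("none", length(hkIds) + length(srIds)))

    n <- length(ids)
    chroms <- paste0("chr", 1:10)
    chrom <- chroms[(seq_len(n) - 1L) %% length(chroms) + 1L]
    strand <- sample(c("+", "-"), n, replace = TRUE)

    # gene-local structure, vectorized by gene category
    isRec <- biotype %in% .RECEPTOR_BIOTYPES
    isSr <- biotype == "smallRNA"
    isStd <- !isRec & !isSr
    e1 <- integer(n); e2s <- rep(NA_integer_, n); e2e <- rep(NA_integer_, n)
    cdsS <- rep(NA_integer_, n); cdsE <- rep(NA_integer_, n)
    nr <- sum(isRec)
    rE1 <- round(runif(nr, 100, 300)); rIn <- round(runif(nr, 1000, 4000))
    rU5 <- round(runif(nr, 50, 150)); rCds <- 3L * round(runif(nr, 300, 320))
    rU3 <- round(runif(nr, 200, 500))
    e1[isRec] <- rE1
    e2s[isRec] <- rE1 + rIn + 1L
    e2e[isRec] <- e2s[isRec] + rU5 + rCds + rU3 - 1L
    cdsS[isRec] <- e2s[isRec] + rU5
    cdsE[isRec] <- cdsS[isRec] + rCds - 1L
    ns <- sum(isStd)
    sE1 <- round(runif(ns, 150, 600)); sIn <- round(runif(ns, 500, 2500))
    sE2 <- round(runif(ns, 300, 1200))
    e1[isStd] <- sE1
    e2s[isStd] <- sE1 + sIn + 1L
    e2e[isStd] <- sE1 + sIn + sE2
    cdsS[isStd] <- e2s[isStd] + 30L
    cdsE[isStd] <- sE1 + sIn + pmax(60L, sE2 - 100L)
    e1[isSr] <- round(runif(sum(isSr), 80, 120))

    # place genes along chromosomes with random gaps
    span <- ifelse(isSr, e1, e2e)
    gap <- round(runif(n, 2000, 8000))
    offset <- integer(n)
    for (ch in chroms) {
        i <- which(chrom == ch)
        sizes <- span[i] + gap[i]
        offset[i] <- 10000L + c(0L, cumsum(head(sizes, -1L)))
    }

    # assemble GRangesLists from the unlisted per-exon vectors
    exS <- rbind(rep(1L, n), e2s); exE <- rbind(e1, e2e)
    keep <- as.vector(!is.na(exS))                 # column-major: per gene in order
    exGene <- rep(seq_len(n), each = 2L)[keep]
    mkGrl <- function(locS, locE, gene) {
        ir <- IRanges(locS + offset[gene] - 1L, locE + offset[gene] - 1L)
        gr <- GRanges(chrom[gene], ir, strand = strand[gene])
        S4Vectors::split(gr, factor(ids[gene], levels = ids))
    }
    exons <- mkGrl(as.vector(exS)[keep], as.vector(exE)[keep], exGene)
    cKeep <- which(!is.na(cdsS))
    cds <- mkGrl(cdsS[cKeep], cdsE[cKeep], cKeep)
    gd <- DataFrame(chrom = chrom, strand = strand, biotype = biotype,
                    homologGroup = homolog, markerClass = markerClass,
                    row.names = ids)
    new("GeneModelSet", exons = exons, cds = cds, geneData = gd)
}

#' Write gene models as GTF
#'
#' Emits `gene`, `exon` and `CDS` features with `gene_id`, `transcript_id`
#' (one transcript per gene), `gene_biotype`, `marker_class` and
#' `homolog_group` attributes, in the standard 1-based inclusive GTF dialect.
#'
#' @param genes a [GeneModelSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGtf <- function(genes, path) {
    ids <- geneIds(genes)
    geneGr <- unlist(range(genes@exons), use.names = FALSE)
    exGr <- unlist(genes@exons, use.names = FALSE)
    cdGr <- unlist(genes@cds, use.names = FALSE)
    gid <- c(ids,
             rep(ids, lengths(genes@exons)),
             rep(ids, lengths(genes@cds)))
    typ <- c(rep("gene", length(geneGr)), rep("exon", length(exGr)),
             rep("CDS", length(cdGr)))
    gr <- c(granges(geneGr), granges(exGr), granges(cdGr))
    idx <- match(gid, ids)
    mcols(gr)$source <- "orcall"
    mcols(gr)$type <- typ
    mcols(gr)$gene_id <- gid
    mcols(gr)$transcript_id <- ifelse(typ == "gene", NA_character_,
                                      paste0(gid, ".t1"))
    mcols(gr)$gene_biotype <- genes@geneData$biotype[idx]
    mcols(gr)$marker_class <- genes@geneData$markerClass[idx]
    mcols(gr)$homolog_group <- genes@geneData$homologGroup[idx]
    mcols(gr)$phase <- ifelse(typ == "CDS", 0L, NA_integer_)
    ord <- order(idx, match(typ, c("gene", "exon", "CDS")), start(gr))
    export(gr[ord], path, format = "gtf")
    invisible(path)
}

#' Read gene models from GTF
#'
#' Inverse of [writeGtf()]: rebuilds a [GeneModelSet-class] from a GTF file
#' carrying `gene_biotype` (and optionally `marker_class`, `homolog_group`)
#' attributes. Exons are sorted by start within each gene.
#'
#' @param path GTF file path.
#' @return a [GeneModelSet-class].
#' @export
readGtf <- function(path) {
    gr <- import(path, format = "gtf")
    gid <- mcols(gr)$gene_id
    ids <- unique(gid)
    getBt <- function(col, default) {
        v <- mcols(gr)[[col]]
        if (is.null(v)) return(setNames(rep(default, length(ids)), ids))
        first <- v[match(ids, gid)]
        setNames(ifelse(is.na(first), default, first), ids)
    }
    typ <- as.character(mcols(gr)$type)
    sortGrl <- function(keep) {
        grl <- S4Vectors::split(granges(gr[keep]), factor(gid[keep], levels = ids))
        GRangesList(lapply(grl, function(g) g[order(start(g))]))
    }
    exons <- sortGrl(typ == "exon")
    cds <- sortGrl(typ == "CDS")
    first <- match(ids, gid)
    gd <- DataFrame(chrom = as.character(seqnames(gr))[first],
                    strand = as.character(strand(gr))[first],
                    biotype = unname(getBt("gene_biotype", "housekeeping")),
                    homologGroup = unname(getBt("homolog_group", NA_character_)),
                    markerClass = unname(getBt("marker_class", "none")),
                    row.names = ids)
    new("GeneModelSet", exons = exons, cds = cds, geneData = gd)
}
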