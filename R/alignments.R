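#' Per-cell read alignments
#'
#' `ReadSet` holds one cell's aligned reads: each read has an assigned gene,
#' a mapping quality, and one or more reference blocks (an `IRangesList`
#' column, multiple blocks meaning the alignment spans an intron). A read is
#' *spliced* iff it has >= 2 blocks.
#'
#' @slot cellId the cell the reads belong to.
#' @slot reads `DataFrame` with columns `read_id`, `gene_id`, `chrom`,
#'   `mapq` and `blocks` (`IRangesList`, sorted non-overlapping reference
#'   intervals per read).
#' @slot decoyTargets gene ids that received homolog-mismapping decoy reads
#'   (low-MAPQ narrow piles) in this cell.
#' @slot contaminationTargets gene ids that received unspliced genomic-DNA
#'   contamination reads in this cell.
#' @export
setClass("ReadSet", representation(
    cellId = "character",
    reads = "DFrame",
    decoyTargets = "character",
    contaminationTargets = "character"
))

setValidity("ReadSet", function(object) {
    msg <- character()
    need <- c("read_id", "gene_id", "chrom", "mapq", "blocks")
    if (!all(need %in% colnames(object@reads)))
        return(paste("reads must have columns", paste(need, collapse = ", ")))
    bl <- object@reads$blocks
    if (length(bl)) {
        ir <- unlist(bl, use.names = FALSE)
        grp <- rep(seq_along(bl), lengths(bl))
        if (length(ir) > 1L) {
            within <- grp[-1] == grp[-length(grp)]
            if (any(within & start(ir)[-1] <= end(ir)[-length(ir)]))
                msg <- c(msg, "blocks must be sorted and non-overlapping within a read")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn ReadSet-class number of reads.
#' @param x a `ReadSet`.
#' @export
setMethod("length", "ReadSet", function(x) nrow(x@reads))

#' @describeIn ReadSet-class compact display.
#' @param object a `ReadSet`.
#' @export
setMethod("show", "ReadSet", function(object) {
    r <- object@reads
    spl <- sum(lengths(r$blocks) >= 2L)
    cat(sprintf("ReadSet for %s: %d reads on %d gene(s); %d spliced; %d decoy / %d contamination target(s)\n",
                object@cellId, nrow(r), length(unique(r$gene_id)), spl,
                length(object@decoyTargets), length(object@contaminationTargets)))
    invisible(object)
})

#' @describeIn ReadSet-class the read table (`DataFrame`).
#' @param readSet a `ReadSet`.
#' @export
readData <- function(readSet) readSet@reads

#' Is each read spliced?
#'
#' @param readSet a [ReadSet-class].
#' @return logical vector, TRUE iff the read has >= 2 alignment blocks.
#' @export
splicedFlag <- function(readSet) lengths(readSet@reads$blocks) >= 2L

# map transcript-coordinate read intervals [s, s+rl-1] to genomic blocks.
# exIr: sorted exon IRanges; returns list(starts, ends, readIdx)
.txReadsToBlocks <- function(exIr, starts, rl) {
    w <- width(exIr)
    cumEnd <- cumsum(w)
    cumStart <- c(0L, head(cumEnd, -1L))
    bs <- integer(0); be <- integer(0); bi <- integer(0)
    for (j in seq_along(starts)) {
        s <- starts[j]; e <- s + rl - 1L
        i1 <- findInterval(s - 1L, cumEnd) + 1L
        i2 <- findInterval(e - 1L, cumEnd) + 1L
        for (i in i1:i2) {
            ts <- max(s, cumStart[i] + 1L)
            te <- min(e, cumEnd[i])
            bs <- c(bs, start(exIr)[i] + (ts - cumStart[i] - 1L))
            be <- c(be, start(exIr)[i] + (te - cumStart[i] - 1L))
            bi <- c(bi, j)
        }
    }
    list(starts = bs, ends = be, readIdx = bi)
}

#' Simulate one cell's read alignments
#'
#' Generates the alignment signatures the receptor caller is designed to
#' distinguish. For each truly expressed receptor of the cell, reads tile the
#' spliced transcript uniformly (plus extra reads proportional to its TPM
#' share of `readsPerCell`), a fixed `highMapqFraction` of them carry high
#' MAPQ, and reads overlapping an exon junction are emitted as two blocks
#' whose gap is exactly the annotated intron. For each non-expressed homolog
#' of an expressed receptor, with probability `homologDecoyRate`, low-MAPQ
#' reads pile up in at most two narrow windows of its CDS (covering well
#' under half of it). With probability `contaminationRate` per cell, one
#' random non-expressed receptor receives unspliced single-block reads
#' scattered over its genomic span, introns included. Deterministic given the
#' cell's stored seed.
#'
#' @param truth a [CohortTruth-class].
#' @param genes the matching [GeneModelSet-class].
#' @param config the [OrSimConfig-class]. `readsPerCell = 0` disables read
#'   simulation (empty read sets, not an error).
#' @param cells cell ids to simulate (default: all).
#' @return named list of [ReadSet-class], one per cell.
#' @export
simulateAlignments <- function(truth, genes, config, cells = cellIds(truth)) {
    stopifnot(is(truth, "CohortTruth"), is(genes, "GeneModelSet"),
              is(config, "OrSimConfig"))
    cd <- cellData(truth)
    idx <- match(cells, cd$cell_id)
    if (anyNA(idx)) stop("unknown cell id(s): ",
                         paste(cells[is.na(idx)], collapse = ", "))
    hg <- homologGroup(genes)
    bt <- geneBiotype(genes)
    chromOf <- setNames(genes@geneData$chrom, geneIds(genes))
    recIds <- .receptorIds(genes)
    rl <- config@readLength
    out <- vector("list", length(cells))
    names(out) <- cells

    for (ci in seq_along(cells)) {
        cell <- cells[ci]
        set.seed(cd$cellSeed[idx[ci]])
        rec <- chosenReceptors(truth, cell)
        expressed <- rec$gene_id
        gAll <- character(); mqAll <- integer()
        bs <- integer(); be <- integer(); biGlobal <- integer()
        nReads <- 0L
        decoyT <- character(); contamT <- character()

        if (config@readsPerCell > 0L) {
            ## truly expressed receptors: uniform transcript tiling
            for (k in seq_along(expressed)) {
                g <- expressed[k]
                exIr <- ranges(exonRanges(genes, g))
                L <- sum(width(exIr))
                if (L <= rl) {
                    starts <- 1L; rlEff <- L
                } else {
                    nTile <- max(2L, ceiling(L / (rl / 2)))
                    extra <- round(config@readsPerCell * rec$true_tpm[k] / 1e6)
                    starts <- round(seq(1L, L - rl + 1L, length.out = nTile))
                    if (extra > 0)
                        starts <- c(starts, sample.int(L - rl + 1L, extra,
                                                       replace = TRUE))
                    rlEff <- rl
                }
                blk <- .txReadsToBlocks(exIr, as.integer(starts), as.integer(rlEff))
                n <- length(starts)
                mq <- rep(config@mapqLow, n)
                nHigh <- ceiling(config@highMapqFraction * n)
                mq[sample.int(n, nHigh)] <- config@mapqHigh
                bs <- c(bs, blk$starts); be <- c(be, blk$ends)
                biGlobal <- c(biGlobal, blk$readIdx + nReads)
                gAll <- c(gAll, rep(g, n)); mqAll <- c(mqAll, mq)
                nReads <- nReads + n
            }

            ## homolog mismapping decoys
            candidates <- unique(unlist(lapply(expressed, function(g) {
                grp <- hg[[g]]
                if (is.na(grp)) return(character())
                setdiff(names(hg)[!is.na(hg) & hg == grp], expressed)
            })))
            for (g in candidates) {
                if (runif(1) >= config@homologDecoyRate) next
                cds <- ranges(cdsRanges(genes, g))
                cs <- min(start(cds)); ce <- max(end(cds))
                if (ce - cs + 1L < rl + 60L) next
                nw <- sample(1:2, 1L)
                wStarts <- sort(round(runif(nw, cs, ce - rl - 20L)))
                n <- config@decoyReads
                per <- ceiling(n / nw)
                rs <- unlist(lapply(wStarts, function(ws)
                    pmin(pmax(ws + round(runif(per, -10, 10)), cs), ce - rl)))
                rs <- rs[seq_len(min(n, length(rs)))]
                n <- length(rs)
                bs <- c(bs, as.integer(rs)); be <- c(be, as.integer(rs + rl - 1L))
                biGlobal <- c(biGlobal, seq_len(n) + nReads)
                gAll <- c(gAll, rep(g, n))
                mqAll <- c(mqAll, rep(config@mapqLow, n))
                nReads <- nReads + n
                decoyT <- c(decoyT, g)
            }

            ## genomic-DNA contamination
            if (runif(1) < config@contaminationRate) {
                pool <- setdiff(recIds, c(expressed, decoyT))
                if (length(pool)) {
                    g <- sample(pool, 1L)
                    exIr <- ranges(exonRanges(genes, g))
                    gs <- min(start(exIr)); ge <- max(end(exIr))
                    n <- config@contaminationReads
                    rs <- sort(round(runif(n, gs, ge - rl)))
                    bs <- c(bs, as.integer(rs)); be <- c(be, as.integer(rs + rl - 1L))
                    biGlobal <- c(biGlobal, seq_len(n) + nReads)
                    gAll <- c(gAll, rep(g, n))
                    mqAll <- c(mqAll, rep(config@mapqHigh, n))
                    nReads <- nReads + n
                    contamT <- g
                }
            }
        }

        blocks <- S4Vectors::split(IRanges(bs, be),
                                   factor(biGlobal, levels = seq_len(nReads)))
        names(blocks) <- NULL
        reads <- DataFrame(
            read_id = if (nReads) sprintf("%s_r%05d", cell, seq_len(nReads)) else character(),
            gene_id = gAll,
            chrom = unname(chromOf[gAll]),
            mapq = mqAll,
            blocks = blocks)
        out[[ci]] <- new("ReadSet", cellId = cell, reads = reads,
                         decoyTargets = decoyT, contaminationTargets = contamT)
    }
    out
}

# chromosome lengths for SAM headers: last annotated base + padding
.chromLengths <- function(genes) {
    ex <- unlist(genes@exons, use.names = FALSE)
    tapply(end(ex), as.character(seqnames(ex)), max) + 10000L
}

#' Write a ReadSet as SAM
#'
#' Plain-text SAM with `@HD`/`@SQ` header, `N` CIGAR operations encoding
#' spliced alignments, the MAPQ field, and an `XG:Z:` tag carrying the gene
#' assignment. No sequences are simulated, so SEQ/QUAL are `*`.
#'
#' @param readSet a [ReadSet-class].
#' @param genes the [GeneModelSet-class] (for reference names and lengths).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSam <- function(readSet, genes, path) {
    cl <- .chromLengths(genes)
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(cl), as.integer(cl)))
    r <- readSet@reads
    lines <- hdr
    if (nrow(r)) {
        cig <- vapply(seq_len(nrow(r)), function(i) {
            b <- r$blocks[[i]]
            w <- width(b)
            if (length(b) == 1L) return(sprintf("%dM", w))
            gaps <- start(b)[-1] - end(b)[-length(b)] - 1L
            paste0(paste0(w[-length(w)], "M", gaps, "N", collapse = ""),
                   w[length(w)], "M")
        }, "")
        pos <- vapply(r$blocks, function(b) start(b)[1], 1L)
        ord <- order(r$chrom, pos)
        body <- sprintf("%s\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*\tXG:Z:%s",
                        r$read_id, r$chrom, pos, r$mapq, cig, r$gene_id)[ord]
        lines <- c(lines, body)
    }
    writeLines(lines, path)
    invisible(path)
}

#' Write one SAM file per cell
#'
#' @param alignments named list of [ReadSet-class] (as returned by
#'   [simulateAlignments()]).
#' @param genes the [GeneModelSet-class].
#' @param dir output directory (created if needed); files are
#'   `<cell_id>.sam`.
#' @return the directory, invisibly.
#' @export
writeSamDir <- function(alignments, genes, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (cell in names(alignments))
        writeSam(alignments[[cell]], genes, file.path(dir, paste0(cell, ".sam")))
    invisible(dir)
}

#' Read a SAM file into a ReadSet
#'
#' Parses alignments (via samtools-equivalent BAM conversion and CIGAR
#' arithmetic), reconstructing one reference block per M stretch with `N`
#' gaps separating blocks. Gene assignment uses the `XG:Z:` tag when present,
#' otherwise the gene whose exons overlap the read most.
#'
#' @param path SAM file.
#' @param genes optional [GeneModelSet-class] for overlap-based gene
#'   assignment when `XG` tags are absent.
#' @param cellId cell id to record (default: file name without extension).
#' @return a [ReadSet-class].
#' @export
readSam <- function(path, genes = NULL, cellId = sub("\\.sam$", "", basename(path))) {
    bam <- suppressMessages(asBam(path, tempfile(), overwrite = TRUE,
                                  indexDestination = FALSE))
    ga <- readGAlignments(bam, param = ScanBamParam(
        tag = "XG", what = c("qname", "mapq")))
    blocks <- extractAlignmentRangesOnReference(cigar(ga), pos = start(ga))
    gene <- mcols(ga)$XG
    if (is.null(gene) || all(is.na(gene))) {
        if (is.null(genes))
            stop("SAM lacks XG gene tags; supply `genes` for overlap assignment")
        gr <- GRanges(seqnames(ga), unlist(blocks))
        grp <- rep(seq_along(ga), lengths(blocks))
        exu <- unlist(genes@exons, use.names = FALSE)
        exGene <- rep(geneIds(genes), lengths(genes@exons))
        hits <- GenomicRanges::findOverlaps(gr, exu)
        ov <- width(IRanges::pintersect(ranges(gr)[S4Vectors::queryHits(hits)],
                                        ranges(exu)[S4Vectors::subjectHits(hits)]))
        df <- data.frame(read = grp[S4Vectors::queryHits(hits)],
                         gene = exGene[S4Vectors::subjectHits(hits)], ov = ov)
        agg <- aggregate(ov ~ read + gene, df, sum)
        agg <- agg[order(agg$read, -agg$ov), ]
        best <- agg[!duplicated(agg$read), ]
        gene <- rep(NA_character_, length(ga))
        gene[best$read] <- best$gene
    }
    reads <- DataFrame(read_id = mcols(ga)$qname,
                       gene_id = as.character(gene),
                       chrom = as.character(seqnames(ga)),
                       mapq = mcols(ga)$mapq,
                       blocks = blocks)
    new("ReadSet", cellId = cellId, reads = reads,
        decoyTargets = character(), contaminationTargets = character())
}
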