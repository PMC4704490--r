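suppressPackageStartupMessages({
    library(S4Vectors)
    library(IRanges)
    library(GenomicRanges)
})

# a small config that keeps simulations fast in unit tests
fastCfg <- function(seed = 1L, nCells = 30L, ...) {
    orSimConfig(seed = seed, nCells = nCells, nOrGenes = 20L,
                nHousekeeping = 100L, ...)
}

# hand-built gene models: two homologous ORs, a housekeeping gene, a smallRNA.
# OlfrT: exons [101,200] + [1001,2000], CDS [1101,1900], intron [201,1000].
toyGenes <- function() {
    exons <- GRangesList(
        OlfrT = GRanges("chr1", IRanges(c(101, 1001), c(200, 2000)), strand = "+"),
        OlfrU = GRanges("chr1", IRanges(c(5001, 6001), c(5100, 7000)), strand = "+"),
        HkT = GRanges("chr1", IRanges(c(9001, 9501), c(9200, 9900)), strand = "+"),
        sRNAT = GRanges("chr1", IRanges(11001, 11100), strand = "+"))
    cds <- GRangesList(
        OlfrT = GRanges("chr1", IRanges(1101, 1900), strand = "+"),
        OlfrU = GRanges("chr1", IRanges(6101, 6900), strand = "+"),
        HkT = GRanges("chr1", IRanges(9531, 9800), strand = "+"),
        sRNAT = GRanges())
    gd <- DataFrame(chrom = "chr1", strand = "+",
                    biotype = c("OR", "OR", "housekeeping", "smallRNA"),
                    homologGroup = c("HG1", "HG1", NA, NA),
                    markerClass = "none",
                    row.names = c("OlfrT", "OlfrU", "HkT", "sRNAT"))
    new("GeneModelSet", exons = exons, cds = cds, geneData = gd)
}

# build a ReadSet by hand from a list of per-read IRanges blocks
mkReadSet <- function(gene_id, blocks, mapq, cell = "cellT", genes = toyGenes()) {
    bl <- IRangesList(blocks)
    names(bl) <- NULL
    chrom <- setNames(genes@geneData$chrom, geneIds(genes))[gene_id]
    reads <- DataFrame(
        read_id = sprintf("%s_r%03d", cell, seq_along(gene_id)),
        gene_id = gene_id, chrom = unname(chrom),
        mapq = as.integer(mapq), blocks = bl)
    new("ReadSet", cellId = cell, reads = reads,
        decoyTargets = character(), contaminationTargets = character())
}

# reads that tile OlfrT's transcript completely, incl. one junction read
toyFullTile <- function(mapqHigh = 50L) {
    blocks <- c(
        lapply(seq(101, 151, by = 25), function(s) IRanges(s, s + 49)),
        list(IRanges(c(161, 1001), c(200, 1060))),      # junction read
        lapply(seq(1001, 1951, by = 25), function(s) IRanges(s, pmin(s + 49, 2000))))
    mkReadSet(rep("OlfrT", length(blocks)), blocks, rep(mapqHigh, length(blocks)))
}

# brute-force per-base membership count over exonic bases (test oracle)
bruteDepth <- function(blockList, exIr) {
    pos <- unlist(Map(seq.int, start(exIr), end(exIr)))
    blocks <- unlist(IRangesList(blockList))
    vapply(pos, function(p) sum(start(blocks) <= p & p <= end(blocks)), 0L)
}

# independent Fisher oracle: explicit factorial formula + table enumeration
fisherEnumOracle <- function(a, b, c, d, tol = 1e-7) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
    lo <- max(0, c1 - r2); hi <- min(c1, r1)
    xs <- lo:hi
    lp <- lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
        lfactorial(N - c1) - lfactorial(N) -
        (lfactorial(xs) + lfactorial(r1 - xs) + lfactorial(c1 - xs) +
         lfactorial(r2 - c1 + xs))
    ps <- exp(lp)
    min(sum(ps[ps <= ps[a - lo + 1] * (1 + tol)]), 1)
}

# shared default-condition simulation (computed once per test run)
.simCache <- new.env(parent = emptyenv())
sharedDefaultSim <- function() {
    if (is.null(.simCache$sim)) {
        cfg <- orSimConfig(seed = 42L, nCells = 60L)
        genes <- generateGeneModels(cfg)
        truth <- simulateCohort(cfg, genes)
        sce <- simulateExpression(truth, genes, cfg)
        tpm <- suppressWarnings(computeTpm(SummarizedExperiment::assay(sce, "tpm"), genes))
        .simCache$sim <- list(cfg = cfg, genes = genes, truth = truth,
                              sce = sce, tpm = tpm)
    }
    .simCache$sim
}
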