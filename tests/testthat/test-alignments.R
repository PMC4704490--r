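test_that("reads of an expressed receptor tile its transcript completely", {
    cfg <- fastCfg(seed = 31, nCells = 40L, homologDecoyRate = 0,
                   contaminationRate = 0)
    genes <- generateGeneModels(cfg)
    truth <- simulateCohort(cfg, genes)
    pos <- cellIds(truth)[cellData(truth)$nReceptors == 1L]
    cell <- pos[1]
    aln <- simulateAlignments(truth, genes, cfg, cells = cell)[[cell]]
    g <- chosenReceptors(truth, cell)$gene_id
    expect_true(all(readData(aln)$gene_id == g))
    prof <- computeCoverage(aln, genes, g)
    expect_true(checkCdsCoverage(prof, genes, g))
    expect_true(all(prof@depth > 0))                       # every exonic base
    expect_gte(mean(readData(aln)$mapq >= 30), 0.9)
    expect_true(checkSpliced(aln, genes, g))               # junction evidence
})

test_that("decoy piles and contamination scatters fail their designed criteria", {
    cfg <- fastCfg(seed = 32, nCells = 60L, homologDecoyRate = 1,
                   contaminationRate = 1)
    genes <- generateGeneModels(cfg)
    truth <- simulateCohort(cfg, genes)
    aln <- simulateAlignments(truth, genes, cfg)
    decoys <- 0L; contams <- 0L
    for (cell in cellIds(truth)) {
        rs <- aln[[cell]]
        for (g in rs@decoyTargets) {
            decoys <- decoys + 1L
            prof <- computeCoverage(rs, genes, g)
            expect_false(checkCdsCoverage(prof, genes, g))  # narrow peaks only
            expect_false(checkMapq(rs, gene = g)$ok)        # low MAPQ piles
        }
        for (g in rs@contaminationTargets) {
            contams <- contams + 1L
            expect_false(checkSpliced(rs, genes, g))        # no junction reads
            expect_true(all(lengths(
                readData(rs)$blocks[readData(rs)$gene_id == g]) == 1L))
        }
    }
    expect_gt(decoys, 5L)
    expect_gt(contams, 3L)
})

test_that("a zero read budget yields empty read sets, not an error", {
    cfg <- fastCfg(seed = 33, nCells = 10L, readsPerCell = 0L)
    genes <- generateGeneModels(cfg)
    truth <- simulateCohort(cfg, genes)
    aln <- simulateAlignments(truth, genes, cfg)
    expect_true(all(vapply(aln, length, 1L) == 0L))
})

test_that("alignment simulation is deterministic per cell and SAM round-trips", {
    cfg <- fastCfg(seed = 34, nCells = 20L)
    genes <- generateGeneModels(cfg)
    truth <- simulateCohort(cfg, genes)
    cell <- cellIds(truth)[cellData(truth)$nReceptors > 0][1]
    a1 <- simulateAlignments(truth, genes, cfg, cells = cell)[[cell]]
    a2 <- simulateAlignments(truth, genes, cfg, cells = cell)[[cell]]
    f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
    writeSam(a1, genes, f1); writeSam(a2, genes, f2)
    expect_identical(readLines(f1), readLines(f2))      # byte-identical SAM
    back <- readSam(f1)
    r1 <- readData(a1); r2 <- readData(back)
    o1 <- order(r1$read_id); o2 <- order(r2$read_id)
    expect_identical(as.list(r1$blocks[o1]), as.list(r2$blocks[o2]))
    expect_identical(r1$mapq[o1], as.integer(r2$mapq[o2]))
    expect_identical(r1$gene_id[o1], r2$gene_id[o2])
})

test_that("spliced flags derive from block counts", {
    rs <- toyFullTile()
    expect_identical(splicedFlag(rs), lengths(readData(rs)$blocks) >= 2L)
    expect_true(any(splicedFlag(rs)))
})
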