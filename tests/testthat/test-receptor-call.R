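test_that("coverage profiles count overlapping blocks correctly", {
    genes <- toyGenes()
    rs <- mkReadSet(c("OlfrT", "OlfrT"),
                    list(IRanges(1101, 1200), IRanges(1151, 1250)),
                    c(50, 50))
    prof <- computeCoverage(rs, genes, "OlfrT")
    d <- setNames(prof@depth, prof@pos)
    expect_true(all(d[as.character(1101:1150)] == 1L))
    expect_true(all(d[as.character(1151:1200)] == 2L))   # overlap
    expect_true(all(d[as.character(1201:1250)] == 1L))
    expect_true(all(d[as.character(101:200)] == 0L))
})

test_that("coverage matches the brute-force per-base oracle on random reads", {
    genes <- toyGenes()
    exIr <- ranges(exonRanges(genes, "OlfrT"))
    set.seed(7)
    for (i in 1:25) {
        starts <- sample(101:1950, 50, replace = TRUE)
        blocks <- lapply(starts, function(s) IRanges(s, min(s + 49, 2000)))
        rs <- mkReadSet(rep("OlfrT", 50), blocks, rep(50, 50))
        prof <- computeCoverage(rs, genes, "OlfrT")
        expect_identical(prof@depth, bruteDepth(blocks, exIr))
    }
})

test_that("blocks outside the gene span are ignored with a message", {
    genes <- toyGenes()
    rs <- mkReadSet(c("OlfrT", "OlfrT"),
                    list(IRanges(1101, 1200), IRanges(3000, 3100)),
                    c(50, 50))
    expect_message(prof <- computeCoverage(rs, genes, "OlfrT"), "outside")
    expect_equal(prof@nIgnored, 1L)
})

test_that("CDS coverage requires every coding base", {
    genes <- toyGenes()
    full <- toyFullTile()
    expect_true(checkCdsCoverage(computeCoverage(full, genes, "OlfrT"), genes))
    # remove coverage of one CDS base (1900)
    r <- readData(full)
    keep <- !vapply(seq_len(nrow(r)), function(i)
        any(start(r$blocks[[i]]) <= 1900 & end(r$blocks[[i]]) >= 1900), TRUE)
    gap <- new("ReadSet", cellId = "cellT", reads = r[keep, ],
               decoyTargets = character(), contaminationTargets = character())
    expect_false(checkCdsCoverage(computeCoverage(gap, genes, "OlfrT"), genes))
    # a gene without CDS cannot be evaluated
    srProf <- computeCoverage(mkReadSet("sRNAT", list(IRanges(11001, 11050)), 50),
                              genes, "sRNAT")
    expect_error(checkCdsCoverage(srProf, genes), "empty CDS")
})

test_that("MAPQ fractions follow the configured dichotomy", {
    expect_equal(checkMapq(c(rep(50, 9), 0), mapqMin = 30),
                 list(fraction = 0.9, ok = TRUE))
    expect_equal(checkMapq(c(rep(50, 4), rep(0, 6)), mapqMin = 30),
                 list(fraction = 0.4, ok = FALSE))   # the sub-50% regime
    expect_true(checkMapq(c(0, 0), fracMin = 0)$ok)  # degenerate threshold
    expect_equal(checkMapq(integer()), list(fraction = 0, ok = FALSE))
})

test_that("splice evidence needs a gap matching an annotated intron exactly", {
    genes <- toyGenes()
    junction <- mkReadSet("OlfrT", list(IRanges(c(161, 1001), c(200, 1060))), 50)
    expect_true(checkSpliced(junction, genes, "OlfrT"))
    unspliced <- mkReadSet("OlfrT", list(IRanges(1101, 1200)), 50)
    expect_false(checkSpliced(unspliced, genes, "OlfrT"))
    # gap endpoints off by one base: not an annotated intron
    off <- mkReadSet("OlfrT", list(IRanges(c(161, 1002), c(200, 1060))), 50)
    expect_false(checkSpliced(off, genes, "OlfrT"))
})

test_that("calls combine the three criteria into the published status rule", {
    genes <- toyGenes()
    full <- toyFullTile()
    call <- callReceptor("cellT", "OlfrT", full, genes, tpm = 1e4)
    expect_equal(call$status, "confident")
    expect_equal(call$n_criteria_met, 3L)
    # CDS + splice pass, MAPQ fraction 0.4: uncertain without rescue
    r <- readData(full)
    lowq <- r; lowq$mapq <- as.integer(ifelse(seq_len(nrow(r)) %% 5 < 2, 50L, 0L))
    rsLow <- new("ReadSet", cellId = "cellT", reads = lowq,
                 decoyTargets = character(), contaminationTargets = character())
    unc <- callReceptor("cellT", "OlfrT", rsLow, genes)
    expect_equal(unc$status, "uncertain")
    expect_lt(unc$mapq_fraction, 0.5)
    # the UTR rescue promotes exactly this pattern
    res <- callReceptor("cellT", "OlfrT", rsLow, genes, utrRescue = TRUE)
    expect_equal(res$status, "confident")
    expect_true(res$utr_rescue)
    # no reads at all: absent
    empty <- mkReadSet(character(), list(), integer())
    expect_equal(callReceptor("cellT", "OlfrT", empty, genes)$status, "absent")
    # non-receptor biotypes are rejected
    expect_error(callReceptor("cellT", "HkT", full, genes), "biotype")
})

test_that("adding full-tile high-MAPQ reads never demotes a confident call", {
    genes <- toyGenes()
    full <- toyFullTile()
    expect_equal(callReceptor("cellT", "OlfrT", full, genes)$status, "confident")
    more <- readData(toyFullTile())
    more$read_id <- paste0(more$read_id, "b")
    doubled <- new("ReadSet", cellId = "cellT",
                   reads = rbind(readData(full), more),
                   decoyTargets = character(), contaminationTargets = character())
    expect_equal(callReceptor("cellT", "OlfrT", doubled, genes)$status, "confident")
})

test_that("cell status follows the uncertainty-blocking rule", {
    mk <- function(status, gene, tpm = 1e4)
        data.frame(cell_id = "c", gene_id = gene, tpm = tpm, status = status)
    expect_equal(classifyCell(rbind(mk("confident", "a"), mk("confident", "b"),
                                    mk("uncertain", "c")))$status, "multi")
    expect_equal(classifyCell(rbind(mk("confident", "a"),
                                    mk("uncertain", "b")))$status, "undetermined")
    expect_equal(classifyCell(mk("uncertain", "a"))$status, "undetermined")
    expect_equal(classifyCell(mk("confident", "a"))$status, "single")
    expect_equal(classifyCell(mk("confident", "a")[0, ])$status, "none")
    expect_equal(classifyCell(mk("absent", "a"))$status, "none")
    expect_error(classifyCell(rbind(mk("confident", "a"), mk("uncertain", "a"))),
                 "duplicate")
    # the optional TPM guard removes low calls before classification
    low <- rbind(mk("confident", "a", tpm = 5), mk("confident", "b", tpm = 1e4))
    expect_equal(classifyCell(low, minTpm = 10)$status, "single")
})
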