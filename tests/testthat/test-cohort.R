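test_that("newborn immature:mature ratio converges to the configured 1.45:1", {
    cfg <- fastCfg(seed = 10, nCells = 10000L, ageMix = 1)  # newborns only
    genes <- generateGeneModels(cfg)
    truth <- simulateCohort(cfg, genes)
    cd <- cellData(truth)
    ratio <- sum(cd$stage == "immature") / sum(cd$stage == "mature")
    expect_gte(ratio, 1.35)
    expect_lte(ratio, 1.55)
})

test_that("a point mass at k = 2 gives every multi cell exactly 2 receptors", {
    cfg <- fastCfg(seed = 11, nCells = 400L,
                   multiK = c(`2` = 1, `3` = 0, `4` = 0, `5` = 0,
                              `6` = 0, `7` = 0, `8` = 0, `9` = 0))
    truth <- simulateCohort(cfg, generateGeneModels(cfg))
    k <- cellData(truth)$nReceptors
    expect_true(any(k > 1))
    expect_true(all(k[k > 1] == 2L))
})

test_that("the default receptor-count distribution has the configured mean", {
    # all cells immature and multi-receptor: k is sampled from multiK directly
    cfg <- fastCfg(seed = 12, nCells = 10000L, ageMix = 1,
                   stageProps = rbind(adult = c(0, 1, 0), newborn = c(0, 1, 0)),
                   receptorPosProb = c(other = 0, immature = 1, mature = 0),
                   multiProb = c(other = 0, immature = 1, mature = 0))
    truth <- simulateCohort(cfg, generateGeneModels(cfg))
    k <- cellData(truth)$nReceptors
    expect_true(all(k >= 2 & k <= 9))
    expect_gte(mean(k), 2.8)
    expect_lte(mean(k), 3.0)
    expect_equal(median(k), 2)
})

test_that("cells choosing the same OR stay within the set-point fold bound", {
    # mature singles only, over 2 ORs, so set points are heavily shared
    cfg <- orSimConfig(seed = 13, nCells = 200L, nOrGenes = 2L, nVrGenes = 0L,
                       nTaarGenes = 0L, nHousekeeping = 50L, ageMix = 0,
                       stageProps = rbind(adult = c(0, 0, 1), newborn = c(0, 0, 1)),
                       receptorPosProb = c(other = 0, immature = 0, mature = 1),
                       multiProb = c(other = 0, immature = 0, mature = 0))
    truth <- simulateCohort(cfg, generateGeneModels(cfg))
    lv <- do.call(rbind, chosenReceptors(truth))
    spread <- tapply(lv$true_tpm, lv$gene_id, function(x) max(x) / min(x))
    expect_true(all(table(lv$gene_id) > 10))
    expect_true(all(spread < 3))
    expect_true(all(lv$true_tpm >= 42.1 & lv$true_tpm <= 1.46e5))
})

test_that("true TPM columns are conserved and receptor counts recorded", {
    truth <- sharedDefaultSim()$truth
    expect_true(all(abs(colSums(trueTpm(truth)) - 1e6) < 1))
    expect_identical(unname(vapply(chosenReceptors(truth), nrow, 1L)),
                     unname(cellData(truth)$nReceptors))
    # stage labels with no receptors: "other" cells are receptor-free
    cd <- cellData(truth)
    expect_true(all(cd$nReceptors[cd$stage == "other"] == 0L))
})

test_that("a stage-probability matrix missing an age is rejected", {
    cfg <- fastCfg()
    sp <- cfg@stageProps
    rownames(sp) <- c("adult", "juvenile")
    cfg@stageProps <- sp
    expect_error(simulateCohort(cfg, generateGeneModels(fastCfg())), "missing age")
})
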