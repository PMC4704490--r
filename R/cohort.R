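#' Ground truth for a simulated cell cohort
#'
#' `CohortTruth` records, per cell, the animal age (`adult`/`newborn`), the
#' developmental stage (`other`/`immature`/`mature`), the chosen receptors
#' with their true expression levels, and the full true TPM vector over all
#' genes (each cell column sums to 1e6). Mature cells carry 0 or 1 receptor
#' except for a small configured fraction that is still multi-receptor;
#' immature receptor-positive cells carry 1 or 2-9 receptors.
#'
#' @slot cellData `DataFrame` with columns `cell_id`, `age`, `stage`,
#'   `nReceptors` and `cellSeed` (per-cell RNG seed used by the read
#'   simulator).
#' @slot receptors named list (one entry per cell) of data frames with
#'   columns `gene_id` and `true_tpm`.
#' @slot trueTpm numeric matrix, genes x cells, true TPM (columns sum 1e6).
#' @export
setClass("CohortTruth", representation(
    cellData = "DFrame",
    receptors = "list",
    trueTpm = "matrix"
))

setValidity("CohortTruth", function(object) {
    msg <- character()
    cd <- object@cellData
    ids <- cd$cell_id
    if (!identical(names(object@receptors), ids) ||
        !identical(colnames(object@trueTpm), ids))
        msg <- c(msg, "receptors and trueTpm must be keyed by cell_id in cellData order")
    nRec <- vapply(object@receptors, nrow, 1L)
    if (!identical(unname(nRec), unname(cd$nReceptors)))
        msg <- c(msg, "nReceptors must match the receptor lists")
    if (any(cd$stage == "mature" & nRec > 9L) || any(nRec > 9L))
        msg <- c(msg, "cells carry at most 9 receptors")
    cs <- colSums(object@trueTpm)
    if (any(abs(cs - 1e6) > 1e-6 * 1e6))
        msg <- c(msg, "true TPM columns must sum to 1e6 (within 1e-6 relative)")
    if (length(msg)) msg else TRUE
})

#' @describeIn CohortTruth-class number of cells.
#' @param x a `CohortTruth`.
#' @export
setMethod("length", "CohortTruth", function(x) nrow(x@cellData))

#' @describeIn CohortTruth-class cell identifiers.
#' @export
setMethod("cellIds", "CohortTruth", function(x) x@cellData$cell_id)

#' @describeIn CohortTruth-class per-cell annotation `DataFrame`.
#' @export
setMethod("cellData", "CohortTruth", function(x) x@cellData)

#' @describeIn CohortTruth-class chosen receptors: the list for one cell
#'   (data frame `gene_id`, `true_tpm`) or the whole named list.
#' @param cell optional single cell id.
#' @export
setMethod("chosenReceptors", "CohortTruth", function(x, cell = NULL)
    if (is.null(cell)) x@receptors else x@receptors[[cell]])

#' @describeIn CohortTruth-class true TPM matrix (genes x cells).
#' @export
setMethod("trueTpm", "CohortTruth", function(x) x@trueTpm)

#' @describeIn CohortTruth-class compact display.
#' @param object a `CohortTruth`.
#' @export
setMethod("show", "CohortTruth", function(object) {
    cd <- object@cellData
    cat("CohortTruth with", nrow(cd), "cells\n")
    print(table(age = cd$age, stage = cd$stage))
    k <- cd$nReceptors
    cat(sprintf("receptor-positive: %d (multi: %d; mean receptors per multi cell %.2f)\n",
                sum(k > 0), sum(k > 1),
                if (any(k > 1)) mean(k[k > 1]) else NA_real_))
    invisible(object)
})

# lognormal truncated to [lo, hi] by resampling (vectorized, exact)
.rlnormTrunc <- function(n, meanlog, sdlog, lo, hi) {
    x <- rlnorm(n, meanlog, sdlog)
    bad <- which(x < lo | x > hi)
    while (length(bad)) {
        x[bad] <- rlnorm(length(bad), meanlog, sdlog)
        bad <- bad[x[bad] < lo | x[bad] > hi]
    }
    x
}

.rdirichlet1 <- function(k, alpha) {
    g <- rgamma(k, shape = alpha)
    if (sum(g) <= 0) g <- rep(1, k)
    g / sum(g)
}

#' Simulate a cell cohort with ground-truth receptor choices
#'
#' Draws each cell's age from `ageMix`, its stage from `stageProps[age, ]`,
#' and its receptor complement from the per-stage receptor-positive and
#' multi-receptor probabilities. Mature single-receptor cells sample their
#' level around the chosen OR's set point so that any two cells choosing the
#' same OR differ by strictly less than `setpointMaxFold`; immature
#' single-receptor cells draw totals around `singleTotalMedian`; multi cells
#' draw k from `multiK`, a total around `multiTotalMedian`, and split it by a
#' Dirichlet weight vector (concentration `dominanceAlpha`, so one OR can
#' dominate). Marker genes get stage-dependent mean levels by class
#' (`immature_only` high in immature cells, `mature_only` in mature, `both`
#' in either, `precursor_only` in "other" cells), and housekeeping genes a
#' fixed relative-abundance profile; the non-receptor budget of each cell is
#' scaled so every true TPM column sums to 1e6.
#'
#' @param config an [OrSimConfig-class].
#' @param genes a [GeneModelSet-class] from [generateGeneModels()] (must
#'   contain at least one receptor gene and all four marker classes).
#' @return a [CohortTruth-class].
#' @examples
#' cfg <- orSimConfig(seed = 1, nCells = 40, nOrGenes = 20, nHousekeeping = 100)
#' truth <- simulateCohort(cfg, generateGeneModels(cfg))
#' truth
#' @export
simulateCohort <- function(config, genes) {
    stopifnot(is(config, "OrSimConfig"), is(genes, "GeneModelSet"))
    recIds <- .receptorIds(genes)
    if (length(recIds) < 1L) stop("gene models contain no receptor genes")
    mcls <- markerClass(genes)
    if (!all(.MARKER_CLASSES %in% mcls))
        stop("gene models must contain all four marker classes")
    missingAges <- setdiff(.AGES, rownames(config@stageProps))
    if (length(missingAges))
        stop("stageProps is missing age(s): ", paste(missingAges, collapse = ", "))
    set.seed(config@seed + 1L)

    n <- config@nCells
    ids <- sprintf("cell_%04d", seq_len(n))
    age <- sample(.AGES, n, replace = TRUE,
                  prob = c(1 - config@ageMix, config@ageMix))
    stage <- vapply(age, function(a)
        sample(.STAGES, 1L, prob = config@stageProps[a, ]), "")
    positive <- runif(n) < config@receptorPosProb[stage]
    multi <- positive & runif(n) < config@multiProb[stage]
    k <- ifelse(!positive, 0L, ifelse(!multi, 1L, NA_integer_))
    nMulti <- sum(is.na(k))
    k[is.na(k)] <- sample(as.integer(names(config@multiK)), nMulti,
                          replace = TRUE, prob = config@multiK)

    # per-OR set point, truncated so the within-OR spread stays inside range
    f <- sqrt(config@setpointMaxFold)
    sp <- setNames(
        .rlnormTrunc(length(recIds), log(config@orLevelMedian), config@orLevelLogSd,
                     config@orLevelRange[1] * f, config@orLevelRange[2] / f),
        recIds)
    fCell <- f * (1 - 1e-6)  # strict < setpointMaxFold between any two cells

    receptors <- vector("list", n)
    names(receptors) <- ids
    for (i in seq_len(n)) {
        ki <- k[i]
        if (ki == 0L) {
            receptors[[i]] <- data.frame(gene_id = character(), true_tpm = numeric())
        } else if (ki == 1L) {
            g <- sample(recIds, 1L)
            lv <- if (stage[i] == "mature")
                sp[[g]] * exp(runif(1, -log(fCell), log(fCell)))
            else
                .rlnormTrunc(1, log(config@singleTotalMedian), config@totalLogSd,
                             config@orLevelRange[1], config@orLevelRange[2])
            receptors[[i]] <- data.frame(gene_id = g, true_tpm = lv)
        } else {
            g <- sample(recIds, ki)
            total <- rlnorm(1, log(config@multiTotalMedian), config@totalLogSd)
            w <- sort(.rdirichlet1(ki, config@dominanceAlpha), decreasing = TRUE)
            receptors[[i]] <- data.frame(gene_id = g, true_tpm = total * w)
        }
    }

    # background transcriptome: stage-dependent marker means + fixed
    # housekeeping profile + small-RNA block, scaled to fill each cell
    allIds <- geneIds(genes)
    bt <- geneBiotype(genes)
    markerIds <- allIds[bt == "marker"]
    hkIds <- allIds[bt == "housekeeping"]
    srIds <- allIds[bt == "smallRNA"]
    markerHigh <- config@markerHighTpm *
        exp(rnorm(length(markerIds), 0, config@markerLevelLogSd))
    onIn <- list(immature_only = "immature", mature_only = "mature",
                 both = c("immature", "mature"), precursor_only = "other")
    markerMeans <- sapply(.STAGES, function(s) {
        on <- vapply(mcls[markerIds], function(cl) s %in% onIn[[cl]], TRUE)
        ifelse(on, markerHigh, config@markerLowTpm)
    })  # markers x stages
    rownames(markerMeans) <- markerIds
    hkWeight <- config@hkMedianTpm * exp(rnorm(length(hkIds), 0, config@hkLevelLogSd))

    tpm <- matrix(0, nrow = length(allIds), ncol = n,
                  dimnames = list(allIds, ids))
    for (i in seq_len(n)) {
        ri <- receptors[[i]]
        recTotal <- sum(ri$true_tpm)
        if (recTotal > 5e5) {  # keep receptors a minority of the transcriptome
            ri$true_tpm <- ri$true_tpm * (5e5 / recTotal)
            receptors[[i]] <- ri
            recTotal <- 5e5
        }
        budget <- 1e6 - recTotal
        srTot <- budget * config@smallRnaWeight
        rest <- budget - srTot
        bg <- c(markerMeans[, stage[i]], hkWeight)
        tpm[c(markerIds, hkIds), i] <- bg * (rest / sum(bg))
        tpm[srIds, i] <- srTot / length(srIds)
        if (nrow(ri)) tpm[ri$gene_id, i] <- ri$true_tpm
    }

    cellSeed <- sample.int(2147483646L, n)
    cd <- DataFrame(cell_id = ids, age = age, stage = unname(stage),
                    nReceptors = k, cellSeed = cellSeed)
    new("CohortTruth", cellData = cd, receptors = receptors, trueTpm = tpm)
}
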