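#' Run the full synthetic analysis pipeline
#'
#' Convenience wrapper chaining the whole desk-side analysis on one
#' configuration: gene models, cohort truth, expression matrix with noise and
#' dropout, per-cell alignments, TPM quantification (small RNAs excluded),
#' receptor calls and per-cell status, rank-PCA staging, and the contingency
#' report.
#'
#' @param config an [OrSimConfig-class].
#' @param classifySeed seed for the stage clustering.
#' @param ... passed to [callReceptors()] (e.g. `mapqMin`, `utrRescue`).
#' @return list with components `genes`, `truth`, `sce` (simulated
#'   expression), `tpm` (quantified, small RNAs excluded), `alignments`,
#'   `calls`, `cellStatus`, `stageScores`, `stages`, `report`.
#' @examples
#' \donttest{
#' res <- runPipeline(orSimConfig(seed = 1, nCells = 60, nOrGenes = 30,
#'                                nHousekeeping = 200))
#' res$report
#' }
#' @export
runPipeline <- function(config, classifySeed = config@seed, ...) {
    genes <- generateGeneModels(config)
    truth <- simulateCohort(config, genes)
    sce <- simulateExpression(truth, genes, config)
    tpm <- suppressWarnings(computeTpm(assay(sce, "tpm"), genes))
    alignments <- simulateAlignments(truth, genes, config)
    calls <- callReceptors(alignments, genes, tpm = tpm, ...)
    cellStatus <- classifyCells(calls, cells = cellIds(truth))
    ranks <- rankTransform(tpm)
    stageScores <- markerPca(ranks, genes)
    stages <- classifyStage(stageScores, seed = classifySeed)
    agesDf <- data.frame(cell_id = cellIds(truth),
                         age = cellData(truth)$age)
    report <- buildReport(stages, cellStatus, agesDf, tpm = tpm)
    list(genes = genes, truth = truth, sce = sce, tpm = tpm,
         alignments = alignments, calls = calls, cellStatus = cellStatus,
         stageScores = stageScores, stages = stages, report = report)
}

#' Write / read a numeric matrix as TSV
#'
#' Plain TSV with gene ids in the first column, the interchange format used
#' for abundance and TPM matrices.
#'
#' @param m numeric matrix with row and column names.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
writeMatrixTsv <- function(m, path) {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeMatrixTsv
#' @export
readMatrixTsv <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
}

#' Write / read the cohort truth table as TSV
#'
#' One row per cell with age, stage and the chosen receptors serialized as
#' `gene:tpm` pairs separated by commas.
#'
#' @param truth a [CohortTruth-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeTruthTsv <- function(truth, path) {
    cd <- as.data.frame(cellData(truth))
    cd$receptors <- vapply(chosenReceptors(truth), function(r)
        paste(sprintf("%s:%.6g", r$gene_id, r$true_tpm), collapse = ","), "")
    write.table(cd, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
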