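#' Simulate an observed abundance matrix with noise and dropout
#'
#' Applies multiplicative lognormal measurement noise to the true TPM matrix,
#' then zeroes entries with a dropout probability driven by the *true*
#' expression level: detection is reliable (dropout ~ `dropoutPHi`) above
#' `dropoutTpmHi` TPM, dropout-dominated (probability >= 0.5) below
#' `dropoutTpmLo`, log-linear in between. Surviving entries of each cell are
#' renormalized to sum 1e6, mimicking the compositional nature of TPM.
#'
#' @param truth a [CohortTruth-class].
#' @param genes the matching [GeneModelSet-class].
#' @param config the [OrSimConfig-class] used to generate `truth`. Set
#'   `noiseSd = 0` and `dropout = FALSE` to obtain the truth matrix exactly.
#' @return a [SingleCellExperiment::SingleCellExperiment] with assays `tpm`
#'   (observed TPM) and `detected` (logical detection mask), `rowData` from
#'   the gene annotation and `colData` from the cohort truth.
#' @examples
#' cfg <- orSimConfig(seed = 1, nCells = 20, nOrGenes = 10, nHousekeeping = 50)
#' genes <- generateGeneModels(cfg)
#' truth <- simulateCohort(cfg, genes)
#' sce <- simulateExpression(truth, genes, cfg)
#' sce
#' @export
simulateExpression <- function(truth, genes, config) {
    stopifnot(is(truth, "CohortTruth"), is(genes, "GeneModelSet"),
              is(config, "OrSimConfig"))
    tt <- trueTpm(truth)
    if (!identical(rownames(tt), geneIds(genes)))
        stop("truth and gene models disagree on the gene universe")
    set.seed(config@seed + 2L)

    obs <- tt
    if (config@noiseSd > 0)
        obs <- obs * matrix(rlnorm(length(tt), 0, config@noiseSd),
                            nrow = nrow(tt))
    if (config@dropout) {
        p <- .dropoutProb(tt, config)
        drop <- matrix(runif(length(tt)) < p, nrow = nrow(tt)) & tt > 0
        obs[drop] <- 0
    }
    cs <- colSums(obs)
    zero <- cs == 0
    if (any(zero))
        warning(sum(zero), " cell(s) have no detected expression; left all-zero")
    obs[, !zero] <- sweep(obs[, !zero, drop = FALSE], 2, cs[!zero] / 1e6, "/")

    SingleCellExperiment(
        assays = list(tpm = obs, detected = obs > 0),
        rowData = genes@geneData,
        colData = cellData(truth))
}

#' Compute TPM with biotype exclusion
#'
#' Removes genes of the excluded biotypes (small RNAs by default, standing in
#' for microRNAs, snoRNAs and rRNAs) *before* rescaling every cell column to
#' sum 1e6, so excluded genes can never alter a retained gene's TPM.
#'
#' @param raw non-negative genes x cells abundance matrix (rownames are gene
#'   ids). Abundances are assumed length-normalized upstream, so TPM reduces
#'   to column rescaling.
#' @param genes a [GeneModelSet-class] supplying biotypes, or a named
#'   character vector of biotypes.
#' @param excludeBiotypes biotypes to drop (default `"smallRNA"`).
#' @return the TPM matrix over retained genes; all-zero cells are left
#'   all-zero with a warning.
#' @examples
#' m <- matrix(c(1, 1, 8), ncol = 1, dimnames = list(c("a", "b", "r"), "c1"))
#' computeTpm(m, c(a = "housekeeping", b = "housekeeping", r = "smallRNA"))
#' @export
computeTpm <- function(raw, genes, excludeBiotypes = "smallRNA") {
    raw <- as.matrix(raw)
    if (any(raw < 0)) stop("abundance matrix must be non-negative")
    bt <- if (is(genes, "GeneModelSet")) geneBiotype(genes) else genes
    if (is.null(rownames(raw)))
        stop("abundance matrix must carry gene ids as rownames")
    keep <- !(bt[rownames(raw)] %in% excludeBiotypes)
    keep[is.na(keep)] <- TRUE  # unannotated genes are retained
    m <- raw[keep, , drop = FALSE]
    cs <- colSums(m)
    zero <- cs == 0
    if (any(zero))
        warning(sum(zero), " cell(s) sum to zero after exclusion; left all-zero")
    m[, !zero] <- sweep(m[, !zero, drop = FALSE], 2, cs[!zero] / 1e6, "/")
    m
}

#' Count detected genes per cell
#'
#' A gene is detected in a cell when its TPM is strictly greater than
#' `threshold` (default 1 TPM; strict, so a gene at exactly 1.0 TPM does not
#' count).
#'
#' @param tpm TPM matrix (genes x cells) or a `SummarizedExperiment` with a
#'   `tpm` assay.
#' @param threshold detection threshold in TPM.
#' @return named integer vector of per-cell counts.
#' @export
detectedGeneCount <- function(tpm, threshold = 1) {
    if (is(tpm, "SummarizedExperiment")) tpm <- assay(tpm, "tpm")
    colSums(tpm > threshold)
}
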