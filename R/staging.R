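#' Rank-transform a TPM matrix across cells
#'
#' For each gene, cells receive the rank of their TPM among all cells
#' (ascending; ties — including shared zeros — get average ranks). Ranking
#' per gene makes the downstream PCA invariant to any monotone per-gene
#' transform of expression, which tames the heavy-tailed noise of single-cell
#' amplification.
#'
#' @param tpm genes x cells matrix (>= 2 cells).
#' @return matrix of the same dimensions containing ranks.
#' @examples
#' rankTransform(matrix(c(0, 5, 10, 0, 0, 7), nrow = 2, byrow = TRUE))
#' @export
rankTransform <- function(tpm) {
    tpm <- as.matrix(tpm)
    if (ncol(tpm) < 2L) stop("ranks are undefined for a single cell")
    r <- t(apply(tpm, 1L, rank, ties.method = "average"))
    dimnames(r) <- dimnames(tpm)
    r
}

#' Stage scores from marker-gene PCA
#'
#' `StageScores` holds the per-cell scores on the first two principal
#' components of the cells x markers rank matrix, the oriented marker
#' loadings, and (after [classifyStage()]) the stage labels.
#'
#' @slot scores `DataFrame`: `cell_id`, `pc1`, `pc2`.
#' @slot loadings `DataFrame`: `gene_id`, `marker_class`, `pc1`, `pc2`.
#' @slot varExplained numeric(2), fraction of variance on PC1/PC2.
#' @export
setClass("StageScores", representation(
    scores = "DFrame", loadings = "DFrame", varExplained = "numeric"))

#' @describeIn StageScores-class compact display.
#' @param object a `StageScores`.
#' @export
setMethod("show", "StageScores", function(object) {
    cat(sprintf("StageScores: %d cells x %d markers; PC1 %.0f%%, PC2 %.0f%% of variance\n",
                nrow(object@scores), nrow(object@loadings),
                100 * object@varExplained[1], 100 * object@varExplained[2]))
    invisible(object)
})

#' PCA on the marker-gene rank matrix
#'
#' Restricts the rank matrix to the marker genes, centers each marker across
#' cells (no variance scaling: ranks already share a scale) and computes
#' principal components. Sign conventions are imposed so the axes are
#' interpretable: PC1 is oriented so the summed loading of `mature_only`
#' markers is positive (mature cells score high on PC1), and PC2 so the
#' summed loading of `immature_only` markers is positive (falling back to
#' `precursor_only` when the set has no immature-only markers, as with
#' bulk-derived sets).
#'
#' @param rankMat rank matrix from [rankTransform()] (genes x cells).
#' @param markers `data.frame` with columns `gene_id` and `marker_class`, or
#'   a [GeneModelSet-class] (its marker-biotype genes are used).
#' @param scale. logical, scale markers to unit variance (default FALSE).
#' @return a [StageScores-class].
#' @export
markerPca <- function(rankMat, markers, scale. = FALSE) {
    if (is(markers, "GeneModelSet")) {
        mc <- markerClass(markers)
        markers <- data.frame(gene_id = names(mc), marker_class = unname(mc))
        markers <- markers[markers$marker_class != "none", ]
    }
    found <- markers$gene_id %in% rownames(rankMat)
    if (!all(found))
        warning(sum(!found), " marker(s) absent from the matrix dropped")
    markers <- markers[found, , drop = FALSE]
    m <- rankMat[markers$gene_id, , drop = FALSE]
    if (ncol(m) < 3L) stop("marker PCA needs >= 3 cells")
    const <- apply(m, 1L, function(x) diff(range(x)) == 0)
    if (any(const)) {
        warning(sum(const), " constant marker row(s) dropped")
        m <- m[!const, , drop = FALSE]
        markers <- markers[!const, , drop = FALSE]
    }
    if (nrow(m) < 2L) stop("fewer than 2 informative markers; PCA is degenerate")
    fit <- prcomp(t(m), center = TRUE, scale. = scale.)
    sc <- fit$x[, 1:2, drop = FALSE]
    ld <- fit$rotation[, 1:2, drop = FALSE]
    orient <- function(axis, classes) {
        for (cl in classes) {
            sel <- markers$marker_class == cl
            if (any(sel)) return(if (sum(ld[sel, axis]) < 0) -1 else 1)
        }
        1
    }
    s1 <- orient(1L, "mature_only")
    s2 <- orient(2L, c("immature_only", "precursor_only"))
    sc[, 1] <- s1 * sc[, 1]; ld[, 1] <- s1 * ld[, 1]
    sc[, 2] <- s2 * sc[, 2]; ld[, 2] <- s2 * ld[, 2]
    ve <- fit$sdev^2 / sum(fit$sdev^2)
    new("StageScores",
        scores = DataFrame(cell_id = colnames(m), pc1 = unname(sc[, 1]),
                           pc2 = unname(sc[, 2])),
        loadings = DataFrame(gene_id = markers$gene_id,
                             marker_class = markers$marker_class,
                             pc1 = unname(ld[, 1]), pc2 = unname(ld[, 2])),
        varExplained = ve[1:2])
}

# default linear boundaries: perpendicular bisectors between kmeans centers,
# each as c(a, b, c) with the rule a*pc1 + b*pc2 + c >= 0
.bisector <- function(from, to) {
    d <- to - from
    mid <- (from + to) / 2
    c(d[1], d[2], -sum(d * mid))
}

#' Classify cells into mature / immature / other
#'
#' Default method: 3-component k-means on (PC1, PC2); the component with the
#' highest mean PC1 is labeled `mature`, the one with the highest mean PC2
#' among the rest `immature`, the remainder `other`. Deterministic given
#' `seed`. Alternative method: two explicit linear boundaries on (PC1, PC2),
#' each `c(a, b, c)` meaning `a*pc1 + b*pc2 + c >= 0`: cells satisfying the
#' first are `mature`; of the rest, cells satisfying the second are
#' `immature`; the remainder `other`. [stageBoundaries()] derives default
#' boundaries from the clustering so they can be perturbed to probe the
#' robustness of downstream conclusions to the exact division line.
#'
#' @param stageScores a [StageScores-class] (>= 3 cells).
#' @param method `"cluster"` (default) or `"boundary"`.
#' @param boundaries list of two numeric(3) vectors for
#'   `method = "boundary"`.
#' @param seed RNG seed for k-means initialization.
#' @return `data.frame`: `cell_id`, `pc1`, `pc2`, `stage`.
#' @export
classifyStage <- function(stageScores, method = c("cluster", "boundary"),
                          boundaries = NULL, seed = 1L) {
    method <- match.arg(method)
    sc <- as.data.frame(stageScores@scores)
    if (nrow(sc) < 3L) stop("stage classification needs >= 3 cells")
    xy <- cbind(sc$pc1, sc$pc2)
    if (method == "cluster") {
        if (nrow(unique(xy)) < 3L)
            stop("degenerate scores: fewer than 3 distinct (pc1, pc2) points")
        set.seed(seed)
        km <- kmeans(xy, centers = 3L, nstart = 25L)
        lab <- .labelClusters(km$centers)
        stage <- lab[km$cluster]
    } else {
        if (is.null(boundaries) || length(boundaries) != 2L)
            stop("method 'boundary' needs a list of two c(a, b, c) boundaries")
        b1 <- boundaries[[1]]; b2 <- boundaries[[2]]
        inMat <- xy[, 1] * b1[1] + xy[, 2] * b1[2] + b1[3] >= 0
        inImm <- xy[, 1] * b2[1] + xy[, 2] * b2[2] + b2[3] >= 0
        stage <- ifelse(inMat, "mature", ifelse(inImm, "immature", "other"))
    }
    data.frame(cell_id = sc$cell_id, pc1 = sc$pc1, pc2 = sc$pc2,
               stage = stage, stringsAsFactors = FALSE)
}

# order 3 cluster centers into stage labels: max PC1 -> mature, then max PC2
# among the rest -> immature
.labelClusters <- function(centers) {
    lab <- rep(NA_character_, 3L)
    mat <- which.max(centers[, 1])
    lab[mat] <- "mature"
    rest <- setdiff(1:3, mat)
    imm <- rest[which.max(centers[rest, 2])]
    lab[imm] <- "immature"
    lab[setdiff(rest, imm)] <- "other"
    lab
}

#' Default stage boundaries from the clustering
#'
#' Returns the two perpendicular-bisector lines between the k-means centers
#' (mature vs immature, and immature vs other), in the `c(a, b, c)` form
#' accepted by [classifyStage()]'s boundary method. `shiftMature` moves the
#' mature/immature line along PC1 by the given fraction of the PC1 range —
#' positive values make the mature class more exclusive.
#'
#' @param stageScores a [StageScores-class].
#' @param seed k-means seed.
#' @param shiftMature fraction of the PC1 range to shift the mature boundary.
#' @return list of two numeric(3) boundaries.
#' @export
stageBoundaries <- function(stageScores, seed = 1L, shiftMature = 0) {
    sc <- stageScores@scores
    xy <- cbind(sc$pc1, sc$pc2)
    if (nrow(unique(xy)) < 3L) stop("degenerate scores: cannot derive boundaries")
    set.seed(seed)
    km <- kmeans(xy, centers = 3L, nstart = 25L)
    lab <- .labelClusters(km$centers)
    cen <- km$centers
    b1 <- .bisector(cen[lab == "immature", ], cen[lab == "mature", ])
    b2 <- .bisector(cen[lab == "other", ], cen[lab == "immature", ])
    if (shiftMature != 0) {
        pc1Range <- diff(range(sc$pc1))
        # move the line along PC1: pc1 -> pc1 - shift changes c by -a*shift
        b1[3] <- b1[3] - b1[1] * shiftMature * pc1Range
    }
    list(b1, b2)
}

#' Select markers from a two-condition bulk FPKM table
#'
#' Reimplements the less-supervised marker selection: keep genes highly
#' expressed (FPKM > `fpkmMin`) in at least one of the two conditions, rank
#' them by pseudocounted fold change `(cond1 + 1) / (cond2 + 1)`, and return
#' the `topN` genes enriched in each direction. With a neuronal-precursor
#' sample in column 1 and a mature-neuron sample in column 2, the returned
#' classes are `precursor_only` and `mature_only`.
#'
#' @param bulk `data.frame` or matrix with exactly two non-negative condition
#'   columns; gene ids in rownames or a `gene_id` column.
#' @param fpkmMin high-expression filter (strictly greater; default 100).
#' @param topN markers per direction (default 100); when fewer genes pass the
#'   filter, all passing genes are returned with a warning.
#' @param classes length-2 marker classes assigned to genes enriched in
#'   condition 1 and condition 2 respectively.
#' @param pseudocount added to both conditions before the ratio (default 1).
#' @return `data.frame` with `gene_id`, `marker_class`, `fold_change`
#'   (condition1-over-condition2, pseudocounted), ordered by direction then
#'   descending enrichment.
#' @export
selectMarkersFromBulk <- function(bulk, fpkmMin = 100, topN = 100,
                                  classes = c("precursor_only", "mature_only"),
                                  pseudocount = 1) {
    if (is.data.frame(bulk) && "gene_id" %in% colnames(bulk)) {
        rownames(bulk) <- bulk$gene_id
        bulk <- bulk[, setdiff(colnames(bulk), "gene_id"), drop = FALSE]
    }
    m <- as.matrix(bulk)
    if (ncol(m) != 2L) stop("bulk table must have exactly 2 condition columns")
    if (any(m < 0)) stop("FPKM values must be non-negative")
    if (is.null(rownames(m))) stop("bulk table must carry gene ids")
    pass <- pmax(m[, 1], m[, 2]) > fpkmMin
    m <- m[pass, , drop = FALSE]
    fc <- (m[, 1] + pseudocount) / (m[, 2] + pseudocount)
    pick <- function(decreasing) {
        ord <- order(fc, decreasing = decreasing)
        n <- min(topN, length(ord))
        if (n < topN)
            warning("only ", n, " gene(s) pass the FPKM filter in one direction")
        ord[seq_len(n)]
    }
    up <- pick(TRUE); dn <- pick(FALSE)
    data.frame(
        gene_id = c(rownames(m)[up], rownames(m)[dn]),
        marker_class = rep(classes, c(length(up), length(dn))),
        fold_change = c(fc[up], fc[dn]),
        row.names = NULL, stringsAsFactors = FALSE)
}
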