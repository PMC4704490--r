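#' Evaluate one receptor in one cell against the three criteria
#'
#' The stringent call requires (i) the coding sequence completely covered
#' (else a truncated, non-coding transcript may have been detected), (ii) a
#' large fraction of reads with high mapping quality (else mismapping from a
#' homologous receptor), and (iii) some reads spanning annotated introns
#' (else genomic-DNA contamination). All three met gives `confident`; 1 or 2
#' gives `uncertain`; none gives `absent`. The optional UTR rescue (off by
#' default) promotes a call whose only failure is the MAPQ fraction to
#' `confident` when the UTR coverage breadth reaches `utrBreadthMin` —
#' mirroring the manual qualification of a recently duplicated receptor whose
#' UTR coverage vouched for true expression.
#'
#' @param cellId cell id (recorded in the output).
#' @param gene receptor gene id; its biotype must be OR, VR or TAAR.
#' @param readSet the cell's [ReadSet-class].
#' @param genes a [GeneModelSet-class].
#' @param tpm the receptor's observed TPM in this cell (annotation only; TPM
#'   plays no role in the criteria).
#' @param mapqMin,fracMin MAPQ criterion parameters (defaults 30 and 0.8).
#' @param utrRescue,utrBreadthMin optional UTR-based rescue.
#' @return one-row `data.frame`: `cell_id`, `gene_id`, `tpm`, `n_reads`,
#'   `cds_covered`, `mapq_fraction`, `mapq_ok`, `spliced_ok`,
#'   `n_criteria_met`, `status`, `utr_rescue`.
#' @export
callReceptor <- function(cellId, gene, readSet, genes, tpm = NA_real_,
                         mapqMin = 30, fracMin = 0.8,
                         utrRescue = FALSE, utrBreadthMin = 0.8) {
    bt <- geneBiotype(genes)[[gene]]
    if (!bt %in% .RECEPTOR_BIOTYPES)
        stop(gene, " has biotype ", bt, "; receptor calls require OR/VR/TAAR")
    prof <- computeCoverage(readSet, genes, gene)
    hasReads <- any(readSet@reads$gene_id == gene)
    cdsOk <- hasReads && checkCdsCoverage(prof, genes, gene)
    mq <- checkMapq(readSet, mapqMin = mapqMin, fracMin = fracMin, gene = gene)
    splOk <- checkSpliced(readSet, genes, gene)
    n <- sum(cdsOk, mq$ok, splOk)
    rescued <- FALSE
    status <- if (n == 3L) "confident" else if (n >= 1L) "uncertain" else "absent"
    if (utrRescue && !mq$ok && cdsOk && splOk &&
        .utrBreadth(prof, genes, gene) >= utrBreadthMin) {
        status <- "confident"
        rescued <- TRUE
    }
    data.frame(cell_id = cellId, gene_id = gene, tpm = tpm,
               n_reads = sum(readSet@reads$gene_id == gene),
               cds_covered = cdsOk, mapq_fraction = mq$fraction,
               mapq_ok = mq$ok, spliced_ok = splOk,
               n_criteria_met = n, status = status, utr_rescue = rescued,
               stringsAsFactors = FALSE)
}

#' Call every receptor with read evidence, across cells
#'
#' Runs [callReceptor()] for each (cell, receptor) pair where the cell's read
#' set contains at least one read assigned to a receptor-biotype gene.
#' Receptors without reads are implicitly `absent` and produce no row.
#'
#' @param alignments named list of [ReadSet-class] (per cell).
#' @param genes a [GeneModelSet-class].
#' @param tpm optional TPM matrix (genes x cells) used to annotate calls.
#' @param ... passed to [callReceptor()] (`mapqMin`, `fracMin`, `utrRescue`,
#'   `utrBreadthMin`).
#' @return `data.frame` of calls, one row per evaluated (cell, receptor).
#' @export
callReceptors <- function(alignments, genes, tpm = NULL, ...) {
    bt <- geneBiotype(genes)
    rows <- list()
    for (cell in names(alignments)) {
        rs <- alignments[[cell]]
        gs <- unique(rs@reads$gene_id)
        gs <- gs[bt[gs] %in% .RECEPTOR_BIOTYPES]
        for (g in gs) {
            tv <- if (!is.null(tpm) && g %in% rownames(tpm) &&
                      cell %in% colnames(tpm)) tpm[g, cell] else NA_real_
            rows[[length(rows) + 1L]] <-
                callReceptor(cell, g, rs, genes, tpm = tv, ...)
        }
    }
    if (length(rows)) do.call(rbind, rows) else
        data.frame(cell_id = character(), gene_id = character(), tpm = numeric(),
                   n_reads = integer(), cds_covered = logical(),
                   mapq_fraction = numeric(), mapq_ok = logical(),
                   spliced_ok = logical(), n_criteria_met = integer(),
                   status = character(), utr_rescue = logical())
}

#' Classify one cell's receptor status
#'
#' From the cell's receptor calls: `multi` when >= 2 confident receptors
#' (additional uncertain calls cannot change that); `single` when exactly 1
#' confident and no uncertain; `none` when no confident and no uncertain
#' calls; `undetermined` when uncertain calls exist and <= 1 confident — the
#' uncertain call could change the category, so the cell is left aside.
#'
#' @param calls `data.frame` of [callReceptor()] rows for one cell.
#' @param minTpm optional TPM guard (default 0): calls with `tpm < minTpm`
#'   are excluded before classification (NA TPM is kept).
#' @return list with `status`, `confident` and `uncertain` gene-id vectors.
#' @export
classifyCell <- function(calls, minTpm = 0) {
    if (anyDuplicated(calls$gene_id))
        stop("duplicate receptor call(s) within one cell: ",
             paste(unique(calls$gene_id[duplicated(calls$gene_id)]), collapse = ", "))
    if (nrow(calls) && minTpm > 0) {
        keep <- is.na(calls$tpm) | calls$tpm >= minTpm
        calls <- calls[keep, , drop = FALSE]
    }
    conf <- calls$gene_id[calls$status == "confident"]
    unc <- calls$gene_id[calls$status == "uncertain"]
    status <- if (length(conf) >= 2L) "multi"
        else if (length(unc) > 0L) "undetermined"
        else if (length(conf) == 1L) "single"
        else "none"
    list(status = status, confident = conf, uncertain = unc)
}

#' Classify receptor status for every cell
#'
#' @param calls `data.frame` from [callReceptors()].
#' @param cells character vector of all cell ids (cells without calls are
#'   `none`).
#' @param minTpm see [classifyCell()].
#' @return `data.frame` with one row per cell: `cell_id`, `status`,
#'   `n_confident`, `n_uncertain`, comma-separated `confident` and
#'   `uncertain` gene lists, and `receptor_tpm` (summed TPM of confident
#'   calls, NA when no TPM annotation was available).
#' @export
classifyCells <- function(calls, cells, minTpm = 0) {
    out <- lapply(cells, function(cell) {
        cc <- calls[calls$cell_id == cell, , drop = FALSE]
        cl <- classifyCell(cc, minTpm = minTpm)
        confTpm <- cc$tpm[cc$status == "confident"]
        data.frame(cell_id = cell, status = cl$status,
                   n_confident = length(cl$confident),
                   n_uncertain = length(cl$uncertain),
                   confident = paste(cl$confident, collapse = ","),
                   uncertain = paste(cl$uncertain, collapse = ","),
                   receptor_tpm = if (length(confTpm)) sum(confTpm) else NA_real_,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
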