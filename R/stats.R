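#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability convention: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' of tables no more probable than the observed one (a relative tolerance of
#' 1e-7 absorbs floating-point ties). The alternative `"doubling"` convention
#' (twice the smaller one-sided tail, capped at 1) is exposed for
#' completeness. The odds ratio is the cross-product `(a*d)/(b*c)`, infinite
#' when `b*c == 0`.
#'
#' @param tab 2x2 matrix of non-negative integer counts `rbind(c(a, b),
#'   c(c, d))` (rows = groups, columns = outcomes).
#' @param method `"point"` (default) or `"doubling"`.
#' @return list with `odds_ratio`, `p_value`, `method`.
#' @examples
#' fisherExactTwoSided(rbind(c(6, 46), c(48, 33)))   # p ~ 2.5e-8
#' @export
fisherExactTwoSided <- function(tab, method = c("point", "doubling")) {
    method <- match.arg(method)
    tab <- as.matrix(tab)
    if (!all(dim(tab) == 2L)) stop("a 2x2 table is required")
    if (any(tab < 0)) stop("counts must be non-negative")
    if (any(tab != round(tab))) stop("counts must be integers")
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    if (a + b + c + d == 0) stop("table total must be positive")
    m <- a + b; n <- c + d; k <- a + c
    lo <- max(0, k - n); hi <- min(k, m)
    x <- lo:hi
    probs <- dhyper(x, m, n, k)
    pObs <- dhyper(a, m, n, k)
    p <- if (method == "point")
        sum(probs[probs <= pObs * (1 + 1e-7)])
    else {
        lower <- sum(probs[x <= a]); upper <- sum(probs[x >= a])
        2 * min(lower, upper)
    }
    or <- if (b * c == 0) {
        if (a * d == 0) NaN else Inf
    } else (a * d) / (b * c)
    list(odds_ratio = or, p_value = min(p, 1), method = paste0("fisher.", method))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Statistic W is the rank sum of `x` in the pooled sample (average ranks for
#' ties). When `length(x) + length(y) <= exactMax` the null distribution of W
#' is obtained by full enumeration of all assignments of the pooled values to
#' the two groups (exact even under ties) and the two-sided p is
#' `2 * min(P(W <= w), P(W >= w))` capped at 1. For larger samples a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y non-empty numeric samples.
#' @param exactMax combined-size cutoff for exact enumeration (default 20).
#' @return list with `statistic` (W), `p_value`, `method`.
#' @examples
#' wilcoxonRankSumTwoSided(c(1, 2, 3), c(10, 20, 30))  # exact p = 0.1
#' @export
wilcoxonRankSumTwoSided <- function(x, y, exactMax = 20) {
    if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
    nx <- length(x); ny <- length(y); N <- nx + ny
    r <- rank(c(x, y), ties.method = "average")
    w <- sum(r[seq_len(nx)])
    if (N <= exactMax) {
        sums <- colSums(matrix(r[combn(N, nx)], nrow = nx))
        eps <- 1e-9 * max(1, abs(w))
        p <- 2 * min(mean(sums <= w + eps), mean(sums >= w - eps))
        list(statistic = w, p_value = min(p, 1), method = "wilcoxon.exact")
    } else {
        mu <- nx * (N + 1) / 2
        ties <- table(r)
        tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
        sigma <- sqrt(nx * ny / 12 * ((N + 1) - tieCorr))
        z <- w - mu
        z <- (z - sign(z) * 0.5) / sigma  # continuity correction
        p <- 2 * pnorm(-abs(z))
        list(statistic = w, p_value = min(p, 1), method = "wilcoxon.normal")
    }
}

#' Proportion with binomial standard error, in percent
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (> 0).
#' @return list with `percent` = 100 k/n and `se_percent` =
#'   100 sqrt(p(1-p)/n).
#' @examples
#' proportionWithSe(15, 55)  # 27.3 +/- 6.0
#' @export
proportionWithSe <- function(k, n) {
    if (n <= 0) stop("n must be positive")
    if (k < 0 || k > n) stop("k must be in [0, n]")
    p <- k / n
    list(percent = 100 * p, se_percent = 100 * sqrt(p * (1 - p) / n))
}

.countTab <- function(f1, f2, lev1, lev2) {
    t <- table(factor(f1, levels = lev1), factor(f2, levels = lev2))
    matrix(as.integer(t), 2, 2, dimnames = dimnames(t))
}

#' Assemble the maturity / multi-receptor report
#'
#' Builds every contingency table and summary linking developmental stage,
#' animal age and receptor status, and runs the corresponding tests:
#'
#' 1. immature:mature ratio per age;
#' 2. Fisher test of stage (immature/mature) x age;
#' 3. Fisher test of receptor status (multi/single) x age, with the
#'    multi-receptor percentage (binomial SE) per age;
#' 4. Fisher test of status (multi/single) x stage among receptor-positive
#'    cells (cells classified `none` or `undetermined` are excluded, and
#'    `other`-stage cells do not enter the two stage rows);
#' 5. Wilcoxon tests of detected-gene counts by age and by status;
#' 6. Wilcoxon test of total receptor TPM, single vs multi;
#' 7. receptor-count summary (mean/median/range) over multi-receptor cells.
#'
#' Degenerate tables (an empty row or column) are computed anyway but
#' flagged with `degenerate = TRUE`.
#'
#' @param stages `data.frame` `cell_id`, `stage` (from [classifyStage()]).
#' @param statuses `data.frame` `cell_id`, `status`, `n_confident`,
#'   `receptor_tpm` (from [classifyCells()]).
#' @param ages `data.frame` `cell_id`, `age`.
#' @param tpm TPM matrix for detected-gene counts (or NULL to skip item 5).
#' @param detectedThreshold TPM detection threshold for item 5.
#' @return an object of class `orReport` (a structured list; see
#'   [print.orReport()]).
#' @export
buildReport <- function(stages, statuses, ages, tpm = NULL,
                        detectedThreshold = 1) {
    cells <- ages$cell_id
    miss <- function(df, what) {
        m <- setdiff(cells, df$cell_id)
        if (length(m)) stop("missing ", what, " for cell(s): ",
                            paste(head(m, 10), collapse = ", "))
    }
    miss(stages, "stage"); miss(statuses, "status")
    d <- data.frame(cell_id = cells,
                    age = ages$age[match(cells, ages$cell_id)],
                    stage = stages$stage[match(cells, stages$cell_id)],
                    status = statuses$status[match(cells, statuses$cell_id)],
                    n_confident = statuses$n_confident[match(cells, statuses$cell_id)],
                    receptor_tpm = statuses$receptor_tpm[match(cells, statuses$cell_id)])

    rep <- list()

    ## 1-2: stage composition by age
    sTab <- .countTab(d$stage[d$stage != "other"], d$age[d$stage != "other"],
                      c("immature", "mature"), c("adult", "newborn"))
    ratio <- sTab["immature", ] / sTab["mature", ]
    rep$stage_by_age <- list(
        table = sTab,
        ratio_immature_to_mature = ratio,
        fisher = fisherExactTwoSided(sTab),
        degenerate = any(rowSums(sTab) == 0) || any(colSums(sTab) == 0))

    ## 3: multi vs single by age
    pos <- d[d$status %in% c("single", "multi"), ]
    aTab <- .countTab(pos$status, pos$age, c("multi", "single"),
                      c("adult", "newborn"))
    prop <- lapply(c(adult = "adult", newborn = "newborn"), function(a) {
        n <- sum(aTab[, a])
        if (n == 0) list(percent = NA_real_, se_percent = NA_real_)
        else proportionWithSe(aTab["multi", a], n)
    })
    rep$status_by_age <- list(
        table = aTab,
        multi_pct = prop,
        fisher = fisherExactTwoSided(aTab),
        degenerate = any(rowSums(aTab) == 0) || any(colSums(aTab) == 0))

    ## 4: multi vs single by stage, receptor-positive cells only
    pos2 <- pos[pos$stage %in% c("immature", "mature"), ]
    gTab <- .countTab(pos2$status, pos2$stage, c("multi", "single"),
                      c("immature", "mature"))
    mProp <- lapply(c(immature = "immature", mature = "mature"), function(s) {
        n <- sum(gTab[, s])
        if (n == 0) list(percent = NA_real_, se_percent = NA_real_)
        else proportionWithSe(gTab["multi", s], n)
    })
    rep$status_by_stage <- list(
        table = gTab,
        multi_pct = mProp,
        fisher = fisherExactTwoSided(gTab),
        degenerate = any(rowSums(gTab) == 0) || any(colSums(gTab) == 0))

    ## 5: detected genes by age and status
    if (!is.null(tpm)) {
        dg <- detectedGeneCount(tpm, detectedThreshold)[d$cell_id]
        rep$detected_genes <- list(
            by_age = if (all(.AGES %in% d$age))
                c(list(median = tapply(dg, d$age, median)),
                  wilcoxonRankSumTwoSided(dg[d$age == "adult"],
                                          dg[d$age == "newborn"]))
                else list(degenerate = TRUE),
            by_status = if (nrow(pos) && all(c("single", "multi") %in% pos$status))
                c(list(median = tapply(dg[match(pos$cell_id, d$cell_id)],
                                       pos$status, median)),
                  wilcoxonRankSumTwoSided(
                      dg[match(pos$cell_id[pos$status == "single"], d$cell_id)],
                      dg[match(pos$cell_id[pos$status == "multi"], d$cell_id)]))
                else list(degenerate = TRUE))
    }

    ## 6: total receptor TPM, single vs multi
    sTpm <- pos$receptor_tpm[pos$status == "single"]
    mTpm <- pos$receptor_tpm[pos$status == "multi"]
    sTpm <- sTpm[!is.na(sTpm)]; mTpm <- mTpm[!is.na(mTpm)]
    rep$receptor_tpm <- if (length(sTpm) && length(mTpm))
        c(list(median_single = median(sTpm), median_multi = median(mTpm)),
          wilcoxonRankSumTwoSided(mTpm, sTpm))
    else list(degenerate = TRUE)

    ## 7: receptors per multi cell
    kMulti <- d$n_confident[d$status == "multi"]
    rep$multi_k <- if (length(kMulti))
        list(n_cells = length(kMulti), mean = mean(kMulti),
             median = median(kMulti), range = range(kMulti))
    else list(degenerate = TRUE, n_cells = 0L)

    class(rep) <- "orReport"
    rep
}

#' Print an orReport
#'
#' @param x an `orReport` from [buildReport()].
#' @param ... ignored.
#' @export
print.orReport <- function(x, ...) {
    fmtP <- function(p) format(signif(p, 2))
    cat("== stage x age ==\n")
    print(x$stage_by_age$table)
    cat(sprintf("immature:mature ratio  adult %.2f : 1, newborn %.2f : 1\n",
                x$stage_by_age$ratio_immature_to_mature[["adult"]],
                x$stage_by_age$ratio_immature_to_mature[["newborn"]]))
    cat("Fisher two-sided p =", fmtP(x$stage_by_age$fisher$p_value), "\n\n")
    cat("== receptor status x age (single/multi cells) ==\n")
    print(x$status_by_age$table)
    for (a in names(x$status_by_age$multi_pct)) {
        pp <- x$status_by_age$multi_pct[[a]]
        cat(sprintf("  %s: multi (%.0f +/- %.0f)%%\n", a, pp$percent, pp$se_percent))
    }
    cat("Fisher two-sided p =", fmtP(x$status_by_age$fisher$p_value), "\n\n")
    cat("== receptor status x stage (single/multi cells) ==\n")
    print(x$status_by_stage$table)
    for (s in names(x$status_by_stage$multi_pct)) {
        pp <- x$status_by_stage$multi_pct[[s]]
        cat(sprintf("  %s: multi (%.0f +/- %.0f)%%\n", s, pp$percent, pp$se_percent))
    }
    if (x$status_by_stage$degenerate) cat("  [degenerate: empty category]\n")
    cat("Fisher two-sided p =", fmtP(x$status_by_stage$fisher$p_value), "\n\n")
    if (!is.null(x$detected_genes)) {
        cat("== detected genes ==\n")
        if (is.null(x$detected_genes$by_age$degenerate))
            cat("by age: medians",
                paste(names(x$detected_genes$by_age$median),
                      round(x$detected_genes$by_age$median), collapse = ", "),
                "| Wilcoxon p =", fmtP(x$detected_genes$by_age$p_value), "\n")
        if (is.null(x$detected_genes$by_status$degenerate))
            cat("by status: medians",
                paste(names(x$detected_genes$by_status$median),
                      round(x$detected_genes$by_status$median), collapse = ", "),
                "| Wilcoxon p =", fmtP(x$detected_genes$by_status$p_value), "\n")
        cat("\n")
    }
    if (is.null(x$receptor_tpm$degenerate))
        cat(sprintf("total receptor TPM: median single %.3g, multi %.3g | Wilcoxon p = %s\n",
                    x$receptor_tpm$median_single, x$receptor_tpm$median_multi,
                    fmtP(x$receptor_tpm$p_value)))
    if (!is.null(x$multi_k$mean))
        cat(sprintf("receptors per multi cell: mean %.2f, median %.1f, range %d-%d (n = %d)\n",
                    x$multi_k$mean, x$multi_k$median,
                    x$multi_k$range[1], x$multi_k$range[2], x$multi_k$n_cells))
    invisible(x)
}

#' Write an orReport as JSON (plus the tables used)
#'
#' @param report an `orReport`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
    clean <- rapply(unclass(report), function(v) {
        if (is.matrix(v)) as.data.frame(v) else v
    }, how = "replace")
    write_json(clean, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}
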