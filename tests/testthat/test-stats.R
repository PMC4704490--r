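test_that("Fisher two-sided p reproduces hand-enumerable tables", {
    expect_equal(fisherExactTwoSided(rbind(c(1, 1), c(1, 1)))$p_value, 1.0)
    # margins (5,5,5,5): only the two extreme tables are as improbable
    expect_equal(fisherExactTwoSided(rbind(c(0, 5), c(5, 0)))$p_value, 2 / 252)
    expect_equal(fisherExactTwoSided(rbind(c(0, 5), c(5, 0)))$odds_ratio, 0)
    expect_equal(fisherExactTwoSided(rbind(c(0, 5), c(0, 5)))$odds_ratio, NaN)
    expect_equal(fisherExactTwoSided(rbind(c(3, 0), c(0, 3)))$odds_ratio, Inf)
    expect_error(fisherExactTwoSided(rbind(c(-1, 1), c(1, 1))), "non-negative")
    expect_error(fisherExactTwoSided(rbind(c(0.5, 1), c(1, 1))), "integers")
})

test_that("Fisher p is invariant to swapping both rows and both columns", {
    set.seed(9)
    for (i in 1:20) {
        t <- matrix(rpois(4, 8), 2)
        p <- fisherExactTwoSided(t)$p_value
        expect_equal(fisherExactTwoSided(t[2:1, ])$p_value, p)
        expect_equal(fisherExactTwoSided(t[, 2:1])$p_value, p)
        expect_equal(fisherExactTwoSided(t(t))$p_value, p)
    }
})

test_that("Fisher agrees with the reference implementation on random tables", {
    set.seed(10)
    for (i in 1:25) {
        t <- matrix(rpois(4, 15), 2)
        if (sum(t) == 0) next
        expect_equal(fisherExactTwoSided(t)$p_value,
                     stats::fisher.test(t)$p.value, tolerance = 1e-7)
    }
})

test_that("Wilcoxon rank-sum matches enumeration on small samples", {
    expect_equal(wilcoxonRankSumTwoSided(c(1, 2, 3), c(10, 20, 30))$p_value, 0.1)
    expect_equal(wilcoxonRankSumTwoSided(c(2, 2, 5), c(2, 2, 5))$p_value, 1.0)
    expect_error(wilcoxonRankSumTwoSided(numeric(), 1:3), "non-empty")
    # untied exact p agrees with the reference implementation
    set.seed(11)
    for (i in 1:10) {
        x <- rnorm(6); y <- rnorm(7)
        expect_equal(wilcoxonRankSumTwoSided(x, y)$p_value,
                     stats::wilcox.test(x, y, exact = TRUE)$p.value,
                     tolerance = 1e-12)
    }
})

test_that("the large-sample Wilcoxon approximation matches the reference", {
    set.seed(12)
    for (i in 1:10) {
        x <- round(rnorm(30, 0, 2)); y <- round(rnorm(25, 0.5, 2))  # many ties
        expect_equal(wilcoxonRankSumTwoSided(x, y)$p_value,
                     suppressWarnings(
                         stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE)$p.value),
                     tolerance = 1e-10)
    }
})

test_that("the exact Wilcoxon test holds its nominal type-I error", {
    set.seed(13)
    rej <- 0L
    for (i in 1:1000) {
        p <- wilcoxonRankSumTwoSided(rnorm(8), rnorm(8))$p_value
        if (p <= 0.05) rej <- rej + 1L
    }
    expect_gte(rej / 1000, 0.03)
    expect_lte(rej / 1000, 0.07)
})

test_that("proportions carry binomial standard errors in percent", {
    p1 <- proportionWithSe(15, 55)
    expect_equal(p1$percent, 27.3, tolerance = 0.01)
    expect_equal(p1$se_percent, 6.0, tolerance = 0.01)
    p2 <- proportionWithSe(5, 43)
    expect_equal(p2$percent, 11.6, tolerance = 0.01)
    expect_equal(p2$se_percent, 4.9, tolerance = 0.01)
    expect_equal(proportionWithSe(0, 10), list(percent = 0, se_percent = 0))
    expect_error(proportionWithSe(1, 0), "positive")
    # SE is maximized at k = n/2
    se <- vapply(0:20, function(k) proportionWithSe(k, 20)$se_percent, 1)
    expect_equal(which.max(se), 11L)  # k = 10
})

# a 178-cell frame reproducing the published marginal counts
paperCohortFrames <- function() {
    age <- c(rep("adult", 56), rep("newborn", 122))
    stage <- c(rep(c("immature", "mature", "other"), c(6, 46, 4)),
               rep(c("immature", "mature", "other"), c(48, 33, 41)))
    status <- c(rep(c("multi", "single", "none"), c(5, 38, 13)),
                rep(c("multi", "single", "none"), c(15, 40, 67)))
    ids <- sprintf("cell_%03d", seq_along(age))
    list(ages = data.frame(cell_id = ids, age = age),
         stages = data.frame(cell_id = ids, stage = stage),
         statuses = data.frame(cell_id = ids, status = status,
                               n_confident = ifelse(status == "multi", 2L,
                                                    ifelse(status == "single", 1L, 0L)),
                               receptor_tpm = NA_real_))
}

test_that("the report reproduces the published ratios from injected counts", {
    fx <- paperCohortFrames()
    rep <- buildReport(fx$stages, fx$statuses, fx$ages)
    expect_equal(rep$stage_by_age$ratio_immature_to_mature[["newborn"]],
                 48 / 33)   # 1.45 : 1
    expect_equal(rep$stage_by_age$ratio_immature_to_mature[["adult"]],
                 6 / 46)    # 0.13 : 1
    expect_identical(unname(rep$stage_by_age$table),
                     matrix(c(6L, 46L, 48L, 33L), 2))
    expect_identical(unname(rep$status_by_age$table),
                     matrix(c(5L, 38L, 15L, 40L), 2))
})

test_that("a cohort without multi cells flags the stage contingency as degenerate", {
    fx <- paperCohortFrames()
    fx$statuses$status[fx$statuses$status == "multi"] <- "single"
    fx$statuses$n_confident[fx$statuses$n_confident > 1L] <- 1L
    rep <- buildReport(fx$stages, fx$statuses, fx$ages)
    expect_true(rep$status_by_stage$degenerate)
    expect_true(rep$status_by_age$degenerate)
    expect_equal(rep$multi_k$n_cells, 0L)
})

test_that("missing cell keys are reported by id", {
    fx <- paperCohortFrames()
    expect_error(buildReport(fx$stages[-1, ], fx$statuses, fx$ages),
                 "cell_001")
})
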