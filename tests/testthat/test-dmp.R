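test_that("group means and delta-beta follow their definitions", {
    x <- c(0.3, 0.5, 0.6, 0.8)
    g <- c("control", "control", "case", "case")
    expect_equal(groupMeans(x, g),
                 c(mean_control = 0.4, mean_case = 0.7))
    expect_equal(groupMeans(rep(0.5, 4), g),
                 c(mean_control = 0.5, mean_case = 0.5))
    expect_error(groupMeans(x[-1], c("control", "case", "case")),
                 "at least 2")

    expect_equal(deltaBeta(0.372, 0.560), 0.188)
    expect_equal(deltaBeta(0.659, 0.387), -0.272)
    expect_equal(deltaBeta(0.5, 0.5), 0)
})

test_that("the two-group F test matches its pooled-t oracle", {
    # hand case frozen from t.test(var.equal = TRUE): t = -3.674235,
    # t^2 = 13.5, p = 0.02131164 on t(4)
    r <- fTest(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
               c("control", "control", "control", "case", "case", "case"))
    expect_equal(unname(r["F_stat"]), 13.5)
    expect_equal(unname(r["p_value"]), 0.02131164, tolerance = 1e-7)

    # equal group means, non-zero variance: F = 0, p = 1
    r0 <- fTest(c(0.2, 0.4, 0.2, 0.4), c("control", "control",
                                         "case", "case"))
    expect_equal(unname(r0["F_stat"]), 0)
    expect_equal(unname(r0["p_value"]), 1)

    # zero within-group variance, unequal means
    expect_warning(
        rz <- fTest(c(0.2, 0.2, 0.4, 0.4),
                    c("control", "control", "case", "case")),
        "zero within-group variance")
    expect_equal(unname(rz["p_value"]), .Machine$double.xmin)
})

test_that("F equals t-squared on 1000 random rows (oracle equivalence)", {
    set.seed(42)
    n1 <- 22; n2 <- 28
    g <- rep(c("control", "case"), c(n1, n2))
    mat <- matrix(rbeta(1000 * (n1 + n2), 2, 2), nrow = 1000)
    r <- methylDMR:::.rowFTest(mat, g)
    for (i in seq_len(nrow(mat))) {
        tt <- t.test(mat[i, g == "case"], mat[i, g == "control"],
                     var.equal = TRUE)
        expect_equal(r$F_stat[i], unname(tt$statistic)^2,
                     tolerance = 1e-10)
        expect_equal(r$p_value[i], tt$p.value, tolerance = 1e-10)
    }
})

test_that("findDMPs emits one genomically sorted record per probe", {
    set.seed(3)
    mat <- matrix(rbeta(5 * 8, 5, 5), 5, 8)
    beta <- makeBetaSet(mat, chrom = c("6", "1", "X", "6", "2"),
                        pos = c(500L, 900L, 100L, 200L, 300L))
    d <- findDMPs(beta)
    expect_equal(nrow(d), 5L)
    expect_identical(d$chrom, c("1", "2", "6", "6", "X"))
    expect_identical(d$pos, c(900L, 300L, 200L, 500L, 100L))
    expect_equal(d$delta_beta, d$mean_case - d$mean_control)
    expect_false(any(d$p_truncated))
})

test_that("prioritisation is a stable, idempotent threshold filter", {
    d <- data.frame(probe_id = c("a", "b", "c", "d"),
                    p_value = c(0.04, 0.04, 0.05, 0.001),
                    delta_beta = c(0.15, 0.05, 0.2, -0.1))
    kept <- prioritizeDMPs(d)
    expect_identical(kept$probe_id, c("a", "d"))  # b fails delta, c fails p
    expect_identical(prioritizeDMPs(kept), kept)  # idempotent
    # |delta| = 0.1 is inclusive, p = 0.05 is strict
    expect_true("d" %in% kept$probe_id)
    expect_false("c" %in% kept$probe_id)
})

test_that("beta spread summary scores genotype-like trimodality", {
    g <- rep(c("control", "case"), each = 5)
    s1 <- betaSpreadSummary(rep(0.5, 10), g)
    expect_equal(s1$trimodality_score, 1)
    s2 <- betaSpreadSummary(seq(0.15, 0.35, length.out = 10), g)
    expect_equal(s2$trimodality_score, 0)
    s3 <- betaSpreadSummary(rep(c(0.05, 0.5, 0.95), length.out = 10), g)
    expect_equal(s3$trimodality_score, 1)
    expect_equal(dim(s1$quantiles), c(2L, 5L))
    expect_equal(unname(s1$quantiles["case", ]), rep(0.5, 5))
})
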