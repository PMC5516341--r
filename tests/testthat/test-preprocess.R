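test_that("background correction subtracts the per-sample control median", {
    meth <- matrix(c(150, 5000), 2, 1)
    unmeth <- matrix(c(2000, 3000), 2, 1)
    raw <- makeRawSet(cbind(meth, meth), cbind(unmeth, unmeth),
                      groups = c("control", "case"),
                      negCtrl = matrix(c(100, 200, 300), 3, 2))
    out <- backgroundCorrect(raw)
    expect_equal(unname(getMeth(out)[, 1]), c(1, 4800))  # 150-200 floored
    expect_equal(unname(getUnmeth(out)[, 1]), c(1800, 2800))

    # all-zero controls: identity (values already >= 1)
    raw0 <- makeRawSet(cbind(meth, meth), cbind(unmeth, unmeth),
                       groups = c("control", "case"),
                       negCtrl = matrix(0, 4, 2))
    expect_equal(getMeth(backgroundCorrect(raw0)), getMeth(raw0))

    expect_error(backgroundCorrect(
        makeRawSet(cbind(meth, meth), cbind(unmeth, unmeth),
                   groups = c("control", "case"))),
        "negative-control")
})

test_that("quantile normalisation equalises distributions, keeps ranks", {
    m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
    out <- quantileNormalize(m)
    expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5))
    expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5))

    # fixed point on identical columns
    m2 <- cbind(c(5, 1, 9), c(5, 1, 9))
    expect_equal(quantileNormalize(m2), m2)

    # definitional property on random input
    set.seed(1)
    r <- matrix(rlnorm(600), 100, 6)
    q <- quantileNormalize(r)
    sorted <- apply(q, 2, sort)
    expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
    for (j in 1:6) expect_equal(rank(q[, j]), rank(r[, j]))
})

test_that("tied values share the average of their block's rank means", {
    m <- cbind(c(1, 1, 10), c(2, 4, 6))
    # sorted-column means: (1.5, 2.5, 8); the tie block in column 1 spans
    # ranks 1-2, so both tied entries get mean(1.5, 2.5) = 2
    out <- quantileNormalize(m)
    expect_equal(unname(out[, 1]), c(2, 2, 8))
})

test_that("quantile normalisation agrees with limma on tie-free data", {
    skip_if_not_installed("limma")
    set.seed(2)
    m <- matrix(rnorm(500), 50, 10)
    expect_equal(unname(quantileNormalize(m)),
                 unname(limma::normalizeQuantiles(m)), tolerance = 1e-12)
})

test_that("beta computation follows M / (M + U + offset)", {
    expect_equal(computeBeta(matrix(0), matrix(0))[1], 0)
    expect_equal(computeBeta(matrix(4900), matrix(0))[1], 0.98)
    expect_equal(computeBeta(matrix(1000), matrix(1000), offset = 0)[1], 0.5)
    expect_error(computeBeta(matrix(-1), matrix(0)), "negative")
    expect_error(computeBeta(matrix(1:2), matrix(1)), "shape")
})

test_that("failed-probe rule is a conjunction over channels and samples", {
    meth <- rbind(c(500, 500), c(500, 1500), c(500, 500))
    unmeth <- rbind(c(500, 500), c(500, 500), c(1500, 1500))
    raw <- makeRawSet(meth, unmeth, groups = c("control", "case"))
    f <- filterFailedProbes(raw)
    expect_identical(f$removed, "cg0001")   # both dim everywhere
    expect_equal(nrow(f$object), 2L)        # one bright sample/channel saves
    # exact threshold is retained (strict <)
    raw2 <- makeRawSet(matrix(1000, 1, 2), matrix(999, 1, 2),
                       groups = c("control", "case"))
    expect_length(filterFailedProbes(raw2)$removed, 0L)
})

test_that("Y and blacklist filters remove exactly the flagged probes", {
    meth <- matrix(2000, 10, 2)
    raw <- makeRawSet(meth, meth, chrom = c(rep("1", 8), "Y", "Y"),
                      groups = c("control", "case"))
    fy <- filterYProbes(raw)
    expect_equal(nrow(fy$object), 8L)
    expect_length(fy$removed, 2L)
    expect_length(filterYProbes(fy$object)$removed, 0L)  # idempotent

    fb <- suppressMessages(
        filterBlacklist(fy$object, c("cg0002", "not_on_array")))
    expect_identical(fb$removed, "cg0002")
    expect_equal(nrow(filterBlacklist(fy$object, character())$object), 8L)
})

test_that("runQC reproduces the generator's truth table exactly", {
    sim <- simulateMethylation(nCase = 4, nControl = 4, nNullProbes = 1500,
        planted = list(plantedDMR("3", 2e6, 4, 50, 0.2)),
        failedFraction = 0.02, yProbeFraction = 0.01,
        blacklistFraction = 0.01, seed = 21)
    qc <- suppressMessages(runQC(sim$raw, sim$blacklist))
    tr <- sim$truth
    cc <- qcCounts(qc$report)
    expect_equal(cc[["n_input"]], nrow(tr))
    expect_equal(cc[["n_failed_removed"]], sum(tr$is_failed))
    expect_equal(cc[["n_y_removed"]], sum(tr$is_y))
    expect_equal(cc[["n_blacklist_removed"]], sum(tr$is_blacklisted))
    expect_setequal(qcRemovedIds(qc$report)$failed,
                    tr$probe_id[tr$is_failed])
    expect_equal(cc[["n_retained"]], nrow(qc$beta))
    b <- getBeta(qc$beta)
    expect_true(all(b >= 0 & b < 1))
})

test_that("a clean dataset passes QC untouched", {
    sim <- simulateMethylation(nCase = 3, nControl = 3, nNullProbes = 200,
        failedFraction = 0, yProbeFraction = 0, blacklistFraction = 0,
        seed = 22)
    qc <- suppressMessages(runQC(sim$raw))
    cc <- qcCounts(qc$report)
    expect_equal(cc[["n_retained"]], cc[["n_input"]])
})
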