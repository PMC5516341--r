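test_that("simulation is deterministic for a fixed seed, on disk included", {
    cfg <- list(nCase = 4, nControl = 4, nNullProbes = 120,
                planted = list(plantedDMR("2", 5e5, 3, 40, 0.2)), seed = 9)
    s1 <- do.call(simulateMethylation, cfg)
    s2 <- do.call(simulateMethylation, cfg)
    expect_identical(getMeth(s1$raw), getMeth(s2$raw))
    expect_identical(getUnmeth(s1$raw), getUnmeth(s2$raw))
    expect_identical(as.data.frame(s1$truth), as.data.frame(s2$truth))

    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeSimulation(s1, d1); writeSimulation(s2, d2)
    f <- list.files(d1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("planted DMRs appear in the truth table with spec'd geometry", {
    sim <- simulateMethylation(nCase = 3, nControl = 3, nNullProbes = 50,
        planted = list(plantedDMR("6", 30039130L, 11, 35, 0.15)), seed = 2)
    tr <- sim$truth
    expect_equal(sum(tr$is_planted), 11L)
    expect_true(all(tr$true_effect[tr$is_planted] == 0.15))
    expect_true(all(tr$true_effect[!tr$is_planted] == 0))
    pp <- tr$pos[tr$is_planted]
    expect_equal(max(pp) - min(pp), 350L)   # (11 - 1) * 35 bp
    expect_true(all(tr$chrom[tr$is_planted] == "6"))
})

test_that("failed/Y/blacklist probes are planted in the promised numbers", {
    sim <- simulateMethylation(nCase = 3, nControl = 3,
        nNullProbes = 2000, failedFraction = 0.01, yProbeFraction = 0.02,
        blacklistFraction = 0.015, seed = 4)
    tr <- sim$truth
    expect_equal(sum(tr$is_failed), round(0.01 * 2000))
    expect_equal(sum(tr$is_y), round(0.02 * 2000))
    expect_equal(sum(tr$is_blacklisted), round(0.015 * 2000))
    expect_setequal(sim$blacklist, tr$probe_id[tr$is_blacklisted])
    expect_true(all(tr$chrom[tr$is_y] == "Y"))
    # failure construction: both channels < 1000 units in every sample
    m <- getMeth(sim$raw); u <- getUnmeth(sim$raw)
    failedIds <- tr$probe_id[tr$is_failed]
    expect_true(all(pmax(m[failedIds, ], u[failedIds, ]) < 1000))
    # and no role overlaps
    expect_equal(max(tr$is_failed + tr$is_y + tr$is_blacklisted), 1L)
})

test_that("generated intensities and betas live on the right scales", {
    sim <- simulateMethylation(nCase = 3, nControl = 3, nNullProbes = 300,
                               seed = 6)
    expect_gte(min(getMeth(sim$raw)), 0)
    expect_gte(min(getUnmeth(sim$raw)), 0)
    b <- computeBeta(getMeth(sim$raw), getUnmeth(sim$raw))
    expect_true(all(b >= 0 & b < 1))
})

test_that("infeasible planted effects are rejected at construction", {
    expect_error(plantedDMR("1", 100L, 3, 10, 0.5, baselineMean = 0.7),
                 "infeasible")
    expect_error(plantedDMR("1", 100L, 1, 10, 0.1), "at least 2")
})

test_that("empiricalEffect reproduces a hand-computed mean difference", {
    # single planted probe, two samples per group
    b <- matrix(c(0.30, 0.40, 0.55, 0.65), nrow = 1,
                dimnames = list("cgX", c("c1", "c2", "t1", "t2")))
    truth <- S4Vectors::DataFrame(probe_id = "cgX", chrom = "1", pos = 1L,
        is_planted = TRUE, true_effect = 0.25, dmr_id = 1L,
        is_failed = FALSE, is_y = FALSE, is_blacklisted = FALSE)
    eff <- empiricalEffect(b, truth,
                           groups = c("control", "control", "case", "case"))
    expect_equal(eff$realised_effect, 0.60 - 0.35)
})

test_that("realised effects track the planted values through the pipeline", {
    # null probes: realised delta-beta centred on zero
    sim0 <- simulateMethylation(nCase = 10, nControl = 10,
                                nNullProbes = 400, seed = 13)
    b0 <- computeBeta(sim0$raw)
    g <- sampleGroups(b0)
    mat <- getBeta(b0)
    delta <- rowMeans(mat[, g == "case"]) - rowMeans(mat[, g == "control"])
    se <- stats::sd(delta) / sqrt(length(delta))
    expect_lt(abs(mean(delta)), 3 * se)

    # planted +0.15 at the default study design; 100 planted probes kept
    # to a realistic minority share (quantile normalisation assumes most
    # probes carry no group difference)
    pl <- lapply(0:9, function(k)
        plantedDMR(as.character(10 + k %% 4), 1e6 + k * 2e5, 10, 35, 0.15))
    sim <- simulateMethylation(nCase = 28, nControl = 22,
        nNullProbes = 4000, planted = pl, seed = 17)
    qc <- suppressMessages(runQC(sim$raw, sim$blacklist))
    eff <- empiricalEffect(qc$beta, sim$truth)
    expect_equal(nrow(eff), 100L)
    expect_lt(abs(mean(eff$realised_effect) - 0.15), 0.02)
})
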