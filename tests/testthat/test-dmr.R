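test_that("the reference DMP set yields the six published regions", {
    dmrs <- callDMRs(rrmsReferenceDMPs())
    expect_length(dmrs, 6L)
    expect_equal(dmrs$n_cpgs, c(6L, 3L, 11L, 3L, 7L, 3L))
    expect_equal(vapply(dmrs$gene_labels, `[`, character(1), 1),
                 c("PM20D1", "HCG4P6", "RNF39", "DRB5", "DRB1", "ERICH1"))
    expect_equal(dmrs$dmr_id, 1:6)
    expect_equal(as.character(GenomicRanges::seqnames(dmrs)),
                 c("1", "6", "6", "6", "6", "8"))
    expect_equal(dmrs$direction,
                 c("hyper", "hyper", "hyper", "hyper", "hypo", "hypo"))
})

test_that("DMR summaries reproduce the published spans and effect sizes", {
    dmrs <- callDMRs(rrmsReferenceDMPs())
    rnf <- dmrs[vapply(dmrs$gene_labels, `[`, character(1), 1) == "RNF39"]
    expect_equal(rnf$span_bp, 346L)
    expect_equal(rnf$max_abs_delta_beta, 0.188)
    hcg <- dmrs[vapply(dmrs$gene_labels, `[`, character(1), 1) == "HCG4P6"]
    expect_equal(hcg$span_bp, 45L)
    drb1 <- dmrs[vapply(dmrs$gene_labels, `[`, character(1), 1) == "DRB1"]
    # hand sum of the seven printed delta-betas: -1.348 / 7
    expect_equal(drb1$mean_delta_beta, -1.348 / 7)
    expect_equal(drb1$direction, "hypo")
})

test_that("chaining boundaries: gap inclusivity, size floor, sign flips", {
    # lone CpG: no region
    expect_length(callDMRs(makeDmps("1", 100, 0.2)), 0L)
    # 1000 bp apart chains, 1001 does not
    expect_length(callDMRs(makeDmps("1", c(100, 1100), c(0.2, 0.2))), 1L)
    expect_length(callDMRs(makeDmps("1", c(100, 1101), c(0.2, 0.2))), 0L)
    # a sign flip severs both potential runs
    expect_length(callDMRs(makeDmps("1", c(100, 150, 200),
                                    c(0.2, -0.2, 0.2))), 0L)
    # chromosomes never chain across
    expect_length(callDMRs(makeDmps(c("1", "2"), c(100, 200),
                                    c(0.2, 0.2))), 0L)
    # duplicate coordinates are a hard error naming the probes
    expect_error(callDMRs(makeDmps("1", c(100, 100), c(0.2, 0.2),
                                   probe_id = c("cgA", "cgB"))),
                 "cgA.*cgB")
    # zero effects cannot be chained
    expect_error(callDMRs(makeDmps("1", c(100, 200), c(0, 0.2))),
                 "non-zero")
})

test_that("greedy chaining equals the exhaustive maximal-interval oracle", {
    # all sign patterns of length <= 4 at tight spacing
    for (len in 2:4) {
        signs <- expand.grid(rep(list(c(-1, 1)), len))
        for (i in seq_len(nrow(signs))) {
            d <- makeDmps("1", seq_len(len) * 100,
                          0.2 * as.numeric(signs[i, ]))
            got <- callDMRs(d)
            want <- oracleDmrMembers(d)
            expect_equal(length(got), length(want))
            expect_identical(lapply(got$probe_ids, as.character), want)
        }
    }
    # randomised inputs up to 12 CpGs with gaps straddling the 1000-bp rule
    set.seed(7)
    for (rep in 1:60) {
        n <- sample(2:12, 1)
        d <- makeDmps(sample(c("1", "2"), 1),
                      cumsum(sample(c(50, 400, 999, 1000, 1001, 2000),
                                    n, replace = TRUE)),
                      sample(c(-0.3, -0.12, 0.12, 0.3), n, replace = TRUE))
        got <- callDMRs(d)
        want <- oracleDmrMembers(d)
        expect_equal(length(got), length(want))
        expect_identical(lapply(got$probe_ids, as.character), want)
    }
})

test_that("DMRs partition the prioritised CpGs they cover", {
    dmrs <- callDMRs(rrmsReferenceDMPs())
    members <- unlist(lapply(dmrs$probe_ids, as.character))
    expect_false(anyDuplicated(members) > 0)
    expect_true(all(members %in% rrmsReferenceDMPs()$probe_id))
    expect_equal(sum(dmrs$n_cpgs), length(members))
    # spans are consistent with member coordinates
    expect_equal(dmrs$span_bp,
                 GenomicRanges::end(dmrs) - GenomicRanges::start(dmrs))
})

test_that("tightening maxGap never grows regions", {
    d <- rrmsReferenceDMPs()
    narrow <- callDMRs(d, maxGap = 10)
    default <- callDMRs(d)
    expect_lte(sum(narrow$n_cpgs), sum(default$n_cpgs))
    expect_lte(max(narrow$n_cpgs), max(default$n_cpgs))
})
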