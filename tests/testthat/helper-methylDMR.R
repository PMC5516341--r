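# Shared fixture builders: everything is constructed in code so no test
# depends on files beyond the packaged reference DMP set.

# A MethylBetaSet from a plain matrix (default group split: first half
# control, second half case).
makeBetaSet <- function(mat, groups = NULL, chrom = NULL, pos = NULL) {
    n <- nrow(mat); k <- ncol(mat)
    if (is.null(rownames(mat))) rownames(mat) <- sprintf("cg%04d", seq_len(n))
    if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%02d", seq_len(k))
    if (is.null(groups))
        groups <- rep(c("control", "case"), c(floor(k / 2), ceiling(k / 2)))
    if (is.null(chrom)) chrom <- rep("1", n)
    if (is.null(pos)) pos <- seq_len(n) * 10000L
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(Beta = mat),
        rowData = S4Vectors::DataFrame(chrom = chrom, pos = as.integer(pos),
            gene = rep("", n), region_label = rep("", n),
            row.names = rownames(mat)),
        colData = S4Vectors::DataFrame(
            group = factor(groups, levels = c("control", "case")),
            row.names = colnames(mat)))
    new("MethylBetaSet", se)
}

# A minimal raw set with explicit channel values and negative controls.
makeRawSet <- function(meth, unmeth, chrom = NULL, negCtrl = NULL,
                       groups = NULL) {
    n <- nrow(meth); k <- ncol(meth)
    rownames(meth) <- rownames(unmeth) <- sprintf("cg%04d", seq_len(n))
    colnames(meth) <- colnames(unmeth) <- sprintf("s%02d", seq_len(k))
    if (is.null(chrom)) chrom <- rep("1", n)
    if (is.null(groups))
        groups <- rep(c("control", "case"), c(floor(k / 2), ceiling(k / 2)))
    man <- data.frame(probe_id = rownames(meth), chrom = chrom,
        pos = seq_len(n) * 10000L, gene = "", region_label = "",
        is_negative_control = FALSE)
    ss <- data.frame(sample_id = colnames(meth), group = groups)
    MethylRawSet(meth, unmeth, man, ss, negativeControls = negCtrl)
}

# DMP-record data.frame for the DMR caller.
makeDmps <- function(chrom, pos, delta, probe_id = NULL, gene = "") {
    n <- length(pos)
    if (is.null(probe_id)) probe_id <- sprintf("cg%05d", seq_len(n))
    data.frame(probe_id = probe_id,
               chrom = rep_len(chrom, n), pos = as.integer(pos),
               gene = rep_len(gene, n), region_label = rep_len("", n),
               F_stat = rep_len(10, n), p_value = rep_len(0.01, n),
               mean_control = rep_len(0.4, n), mean_case = 0.4 + delta,
               delta_beta = delta, p_truncated = rep_len(FALSE, n))
}

# Independent DMR oracle: enumerate every contiguous interval of the
# genomically sorted records, keep those whose every adjacent pair is
# linkable (same chrom, gap <= maxGap, same delta sign) and that satisfy
# the size floor, then retain the maximal ones.  O(n^2) by construction,
# shares no code with callDMRs().
oracleDmrMembers <- function(df, maxGap = 1000, minCpgs = 2) {
    df <- df[order(methylDMR:::chromRank(df$chrom), df$pos), ]
    n <- nrow(df)
    linkable <- function(i, j)
        df$chrom[i] == df$chrom[j] && (df$pos[j] - df$pos[i]) <= maxGap &&
        sign(df$delta_beta[i]) == sign(df$delta_beta[j])
    valid <- list()
    for (i in seq_len(n)) for (j in i:n) {
        if (j - i + 1 < minCpgs) next
        ok <- TRUE
        for (q in i:(j - 1)) if (!linkable(q, q + 1)) { ok <- FALSE; break }
        if (ok) valid[[length(valid) + 1]] <- i:j
    }
    # maximal: not contained in another valid interval
    keep <- vapply(valid, function(iv) {
        !any(vapply(valid, function(other)
            length(other) > length(iv) && all(iv %in% other), logical(1)))
    }, logical(1))
    lapply(valid[keep], function(iv) df$probe_id[iv])
}
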