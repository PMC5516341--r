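#' Per-group mean betas
#'
#' @param x numeric vector of beta values for one CpG.
#' @param groups factor/character of \code{"control"} / \code{"case"} per
#'   entry of \code{x}; each group needs >= 2 members.
#' @return named numeric vector \code{c(mean_control, mean_case)}.
#' @export
groupMeans <- function(x, groups) {
    groups <- factor(as.character(groups), levels = c("control", "case"))
    if (any(table(groups) < 2L))
        stop("each group needs at least 2 members")
    c(mean_control = mean(x[groups == "control"]),
      mean_case = mean(x[groups == "case"]))
}

#' Delta-beta effect size
#'
#' Case group mean beta minus control group mean beta; ranges over
#' [-1, 1] and reads as the absolute methylation difference (e.g. 0.188 =
#' 18.8 percentage points more methylated in cases).
#'
#' @param meanControl,meanCase group mean betas in [0, 1].
#' @return signed numeric.
#' @examples
#' deltaBeta(0.372, 0.560)   # 0.188
#' @export
deltaBeta <- function(meanControl, meanCase) {
    stopifnot(all(meanControl >= 0 & meanControl <= 1),
              all(meanCase >= 0 & meanCase <= 1))
    meanCase - meanControl
}

# Vectorised two-group one-way ANOVA over matrix rows.
# Returns F with df (1, n-2) and its upper-tail p; for two groups F equals
# the squared pooled-variance t statistic.
.rowFTest <- function(mat, groups) {
    groups <- factor(as.character(groups), levels = c("control", "case"))
    n1 <- sum(groups == "control"); n2 <- sum(groups == "case")
    if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 members")
    n <- n1 + n2
    m1 <- rowMeans(mat[, groups == "control", drop = FALSE])
    m2 <- rowMeans(mat[, groups == "case", drop = FALSE])
    gm <- (n1 * m1 + n2 * m2) / n
    ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
    ssw <- rowSums((mat - ifelse(matrix(groups == "control", nrow(mat), n,
                                        byrow = TRUE), m1, m2))^2)
    msb <- ssb / 1
    msw <- ssw / (n - 2)
    f <- msb / msw
    p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
    # degenerate rows: no within-group variance
    zeroW <- msw == 0
    if (any(zeroW)) {
        eq <- zeroW & (ssb == 0)
        f[eq] <- 0; p[eq] <- 1
        ne <- zeroW & (ssb > 0)
        if (any(ne)) {
            f[ne] <- Inf
            p[ne] <- .Machine$double.xmin
            warning(sum(ne), " probe(s) with zero within-group variance ",
                    "and unequal means; p set to the smallest positive value")
        }
    }
    list(F_stat = f, p_value = p,
         mean_control = m1, mean_case = m2)
}

#' Two-group ANOVA F test for one CpG
#'
#' One-way ANOVA with two groups: F = between-group mean square /
#' within-group mean square on (1, n-2) degrees of freedom, p from the
#' upper tail of the F distribution.  Algebraically identical to the
#' squared pooled-variance two-sample t statistic.  Degenerate rows with
#' zero within-group variance yield F = 0, p = 1 when the group means are
#' equal, and p equal to the smallest representable positive value (with a
#' warning) when they differ.
#'
#' @param x numeric vector of beta values for one CpG (n >= 4).
#' @param groups factor/character of \code{"control"} / \code{"case"}.
#' @return named numeric vector \code{c(F_stat, p_value)}.
#' @examples
#' fTest(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
#'       rep(c("control", "case"), each = 3))
#' @export
fTest <- function(x, groups) {
    r <- .rowFTest(matrix(x, nrow = 1), groups)
    c(F_stat = unname(r$F_stat), p_value = unname(r$p_value))
}

#' Test every CpG for differential methylation
#'
#' Runs the two-group ANOVA F test on each row of a beta matrix and
#' assembles one DMP record per probe: manifest annotation, F statistic,
#' p-value, group mean betas and delta-beta.  Records are sorted by
#' genomic position (chromosome, then bp).
#'
#' No multiple-testing correction is applied here: the intended workflow
#' prioritises nominal p-values jointly with an effect-size threshold
#' ([prioritizeDMPs()]) and a regional-consistency requirement
#' ([callDMRs()]) rather than a genome-wide error rate.
#'
#' @param beta a \linkS4class{MethylBetaSet} (post-QC).
#' @return a [S4Vectors::DataFrame] with columns \code{probe_id},
#'   \code{chrom}, \code{pos}, \code{gene}, \code{region_label},
#'   \code{F_stat}, \code{p_value}, \code{mean_control}, \code{mean_case},
#'   \code{delta_beta}, \code{p_truncated} (always \code{FALSE} for
#'   computed records).
#' @export
findDMPs <- function(beta) {
    stopifnot(is(beta, "MethylBetaSet"))
    mat <- getBeta(beta)
    groups <- sampleGroups(beta)
    r <- .rowFTest(mat, groups)
    man <- probeManifest(beta)
    out <- S4Vectors::DataFrame(
        probe_id = man$probe_id, chrom = man$chrom, pos = man$pos,
        gene = man$gene, region_label = man$region_label,
        F_stat = unname(r$F_stat), p_value = unname(r$p_value),
        mean_control = unname(r$mean_control),
        mean_case = unname(r$mean_case),
        delta_beta = unname(r$mean_case - r$mean_control),
        p_truncated = rep(FALSE, nrow(man)))
    out[genomicOrder(out$chrom, out$pos), ]
}

#' Prioritise DMPs by p-value and effect size
#'
#' Retains records with \code{p_value < pThreshold} (strict) and
#' \code{|delta_beta| >= deltaThreshold} (inclusive).  A pure filter:
#' order is preserved and the operation is idempotent.
#'
#' @param dmps a DataFrame/data.frame of DMP records (see [findDMPs()]).
#' @param pThreshold nominal p-value cutoff (default 0.05).
#' @param deltaThreshold minimum absolute delta-beta (default 0.1).
#' @return the filtered records.
#' @export
prioritizeDMPs <- function(dmps, pThreshold = 0.05, deltaThreshold = 0.1) {
    keep <- dmps$p_value < pThreshold &
        abs(dmps$delta_beta) >= deltaThreshold
    dmps[keep, ]
}

#' Per-group beta spread and trimodality summary
#'
#' Summarises the per-sample beta distribution of one CpG within each
#' group (min, quartiles, max) together with a trimodality score: the
#' proportion of samples lying within 0.1 of the nearest of {0, 0.5, 1}.
#' SNP-driven signals produce genotype-like beta clusters at those three
#' anchors (score near 1 with wide spread), whereas a genuine group-mean
#' shift leaves an even spread within each group.
#'
#' @param x numeric vector of beta values for one CpG.
#' @param groups factor/character of \code{"control"} / \code{"case"}.
#' @return list with \code{quantiles} (2 x 5 matrix, rows control/case)
#'   and \code{trimodality_score} (overall proportion).
#' @export
betaSpreadSummary <- function(x, groups) {
    groups <- factor(as.character(groups), levels = c("control", "case"))
    q <- t(vapply(levels(groups), function(g)
        stats::quantile(x[groups == g], c(0, 0.25, 0.5, 0.75, 1)),
        numeric(5)))
    anchorDist <- pmin(abs(x - 0), abs(x - 0.5), abs(x - 1))
    list(quantiles = q,
         trimodality_score = mean(anchorDist <= 0.1))
}
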