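#' Specify a planted DMR for the simulator
#'
#' Describes one contiguous run of CpGs whose case-group methylation is
#' shifted by a fixed amount on the beta scale, emulating the regional
#' structure of published case-control DMRs (a handful of CpGs tens of bp
#' apart with |delta-beta| around 0.1-0.27).
#'
#' @param chrom chromosome label (bare, e.g. \code{"6"}).
#' @param startPos 1-based position of the first CpG.
#' @param nCpgs number of CpGs in the region (>= 2).
#' @param spacingBp distance in bp between consecutive CpGs (>= 1).
#' @param effect target delta-beta (case mean minus control mean); signed.
#' @param baselineMean control-group mean beta, in (0, 1);
#'   \code{baselineMean + effect} must also lie in (0, 1).
#' @return a \code{plantedDMR} list usable in [simulateMethylation()].
#' @examples
#' plantedDMR("6", 30039130L, nCpgs = 11, spacingBp = 35, effect = 0.15)
#' @export
plantedDMR <- function(chrom, startPos, nCpgs, spacingBp, effect,
                       baselineMean = 0.35) {
    stopifnot(is.character(chrom), nzchar(chrom), length(chrom) == 1L)
    startPos <- as.integer(startPos)
    nCpgs <- as.integer(nCpgs)
    spacingBp <- as.integer(spacingBp)
    if (startPos < 1L) stop("startPos must be >= 1")
    if (nCpgs < 2L) stop("a planted DMR needs at least 2 CpGs")
    if (spacingBp < 1L) stop("spacingBp must be >= 1")
    if (baselineMean <= 0 || baselineMean >= 1)
        stop("baselineMean must lie strictly in (0, 1)")
    shifted <- baselineMean + effect
    if (shifted <= 0 || shifted >= 1)
        stop("infeasible effect: baselineMean + effect = ", shifted,
             " is outside (0, 1)")
    structure(list(chrom = chrom, startPos = startPos, nCpgs = nCpgs,
                   spacingBp = spacingBp, effect = effect,
                   baselineMean = baselineMean),
              class = "plantedDMR")
}

# Restore the caller's RNG state on exit so simulation seeds stay local.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Simulate a 450K-like two-group methylation dataset
#'
#' Generates paired methylated/unmethylated intensity matrices for a
#' case-control study with known ground truth.  Per probe \eqn{i} and
#' sample \eqn{j}, the true methylation fraction \eqn{m_{ij}} is drawn from
#' a Beta distribution parameterised by mean and concentration
#' (\eqn{a = \mu c}, \eqn{b = (1-\mu)c}, \eqn{c =} \code{betaPrecision});
#' case samples at planted CpGs have their mean shifted by the planted
#' effect, directly on the beta (delta-beta) scale.  A per-observation
#' total intensity \eqn{T_{ij}} is drawn log-normal, split into
#' \eqn{T_{ij} m_{ij}} (methylated) and \eqn{T_{ij}(1-m_{ij})}
#' (unmethylated), and half-normal background noise with scale 5\% of the
#' median total intensity is added to each channel.  The same background
#' distribution yields 96 negative-control intensities per sample.
#'
#' A fraction of non-planted probes is made to fail (both channels rescaled
#' below 1000 units in every sample), a fraction is relabelled to
#' chromosome Y, and a fraction is emitted into a cross-reactive blacklist;
#' the three sets are disjoint and never touch planted probes.  Null probes
#' are laid out with inter-probe spacing of at least 2 kb (and kept at
#' least 2 kb away from planted regions), so chance regional clusters
#' cannot arise from the layout itself.  Per-probe baseline means for null
#' probes are drawn from a rescaled Beta(2, 2) on [0.1, 0.9].
#'
#' Output is deterministic for a fixed \code{seed}; the caller's RNG state
#' is left untouched.
#'
#' @param nCase,nControl group sizes (each >= 2).  Defaults mirror a
#'   28-case / 22-control CD4+ T-cell study design.
#' @param nNullProbes number of probes with no planted effect.
#' @param planted list of [plantedDMR()] specifications.
#' @param betaPrecision Beta-distribution concentration (a + b) shared by
#'   all probes; larger means less biological spread per CpG.
#' @param totalIntensityLogMean,totalIntensityLogSd log-normal parameters
#'   of the per-observation total intensity, in log-units.
#' @param failedFraction,yProbeFraction,blacklistFraction fractions of the
#'   total probe count to fail / place on chrY / blacklist (each in [0, 1),
#'   jointly < 1 of the null-probe count).
#' @param seed integer RNG seed.
#' @return a list with elements \code{raw} (a \linkS4class{MethylRawSet}
#'   including negative controls), \code{blacklist} (character vector of
#'   probe ids) and \code{truth} (a [S4Vectors::DataFrame] with one row per
#'   probe: \code{probe_id}, \code{chrom}, \code{pos}, \code{is_planted},
#'   \code{true_effect}, \code{dmr_id}, \code{is_failed}, \code{is_y},
#'   \code{is_blacklisted}, in the same order as \code{raw}).
#' @examples
#' sim <- simulateMethylation(nCase = 4, nControl = 4, nNullProbes = 50,
#'     planted = list(plantedDMR("6", 1e6, 3, 50, 0.2)), seed = 7)
#' sim$raw
#' sum(sim$truth$is_planted)
#' @export
simulateMethylation <- function(nCase = 28, nControl = 22,
                                nNullProbes = 10000, planted = list(),
                                betaPrecision = 50,
                                totalIntensityLogMean = log(8000),
                                totalIntensityLogSd = 0.3,
                                failedFraction = 0.01,
                                yProbeFraction = 0.01,
                                blacklistFraction = 0.01,
                                seed = 1L) {
    nCase <- as.integer(nCase); nControl <- as.integer(nControl)
    if (nCase < 2L || nControl < 2L)
        stop("each group needs at least 2 samples")
    if (!all(vapply(planted, inherits, logical(1), "plantedDMR")))
        stop("'planted' must be a list of plantedDMR() specifications")
    fr <- c(failedFraction, yProbeFraction, blacklistFraction)
    if (any(fr < 0) || any(fr >= 1))
        stop("probe fractions must lie in [0, 1)")
    nPlanted <- sum(vapply(planted, `[[`, integer(1), "nCpgs"))
    nTotal <- nNullProbes + nPlanted
    nFailed <- round(failedFraction * nTotal)
    nY <- round(yProbeFraction * nTotal)
    nBlack <- round(blacklistFraction * nTotal)
    if (nFailed + nY + nBlack > nNullProbes)
        stop("failed/Y/blacklist fractions exceed the null-probe budget")

    .withSeed(seed, {
        nSamp <- nCase + nControl
        group <- factor(rep(c("control", "case"), c(nControl, nCase)),
                        levels = c("control", "case"))
        sampleIds <- c(sprintf("ctrl_%02d", seq_len(nControl)),
                       sprintf("case_%02d", seq_len(nCase)))

        # planted probe coordinates and effects
        pChrom <- character(0); pPos <- integer(0)
        pEffect <- numeric(0); pBase <- numeric(0); pDmr <- integer(0)
        for (k in seq_along(planted)) {
            sp <- planted[[k]]
            pos <- sp$startPos + sp$spacingBp * (seq_len(sp$nCpgs) - 1L)
            pChrom <- c(pChrom, rep(sp$chrom, sp$nCpgs))
            pPos <- c(pPos, pos)
            pEffect <- c(pEffect, rep(sp$effect, sp$nCpgs))
            pBase <- c(pBase, rep(sp$baselineMean, sp$nCpgs))
            pDmr <- c(pDmr, rep(k, sp$nCpgs))
        }
        pId <- sprintf("cgD%02d_%03d", pDmr, unlist(lapply(
            vapply(planted, `[[`, integer(1), "nCpgs"), seq_len)))

        # null probe layout: >= 2 kb spacing, steered clear of planted
        # regions so adjacency is impossible by construction
        nChrom <- sample(as.character(1:22), nNullProbes, replace = TRUE)
        nPos <- integer(nNullProbes)
        for (ch in unique(nChrom)) {
            idx <- which(nChrom == ch)
            gaps <- sample(2000:50000, length(idx), replace = TRUE)
            pos <- 1000000L + cumsum(gaps)
            keep <- which(pChrom == ch)
            if (length(keep)) {
                lo <- min(pPos[keep]) - 2000L
                hi <- max(pPos[keep]) + 2000L
                pos[pos >= lo & pos <= hi] <- pos[pos >= lo & pos <= hi] +
                    (hi - lo) + 2000L
            }
            nPos[idx] <- pos
        }
        nId <- sprintf("cgN%06d", seq_len(nNullProbes))

        # special null-probe roles, disjoint
        special <- sample(nNullProbes, nFailed + nY + nBlack)
        failedIdx <- special[seq_len(nFailed)]
        yIdx <- special[nFailed + seq_len(nY)]
        blackIdx <- special[nFailed + nY + seq_len(nBlack)]
        if (nY) {
            nChrom[yIdx] <- "Y"
            nPos[yIdx] <- 1000000L + cumsum(sample(2000:50000, nY,
                                                   replace = TRUE))
        }

        chrom <- c(nChrom, pChrom)
        pos <- c(nPos, pPos)
        probeId <- c(nId, pId)
        baseline <- c(0.1 + 0.8 * stats::rbeta(nNullProbes, 2, 2), pBase)
        effect <- c(rep(0, nNullProbes), pEffect)
        dmrId <- c(rep(NA_integer_, nNullProbes), pDmr)
        isFailed <- c(seq_len(nNullProbes) %in% failedIdx,
                      rep(FALSE, nPlanted))
        isY <- c(seq_len(nNullProbes) %in% yIdx, rep(FALSE, nPlanted))
        isBlack <- c(seq_len(nNullProbes) %in% blackIdx,
                     rep(FALSE, nPlanted))

        # methylation fractions: Beta(mean, concentration) per cell
        mu <- matrix(baseline, nTotal, nSamp)
        mu[, group == "case"] <- mu[, group == "case"] + effect
        m <- matrix(stats::rbeta(nTotal * nSamp, mu * betaPrecision,
                                 (1 - mu) * betaPrecision),
                    nTotal, nSamp)

        # channel intensities
        tot <- matrix(stats::rlnorm(nTotal * nSamp, totalIntensityLogMean,
                                    totalIntensityLogSd), nTotal, nSamp)
        bgScale <- 0.05 * stats::median(tot)
        meth <- tot * m + abs(matrix(stats::rnorm(nTotal * nSamp, 0,
                                                  bgScale), nTotal, nSamp))
        unmeth <- tot * (1 - m) + abs(matrix(stats::rnorm(nTotal * nSamp, 0,
                                                  bgScale), nTotal, nSamp))

        # failed probes: rescale both channels below the 1000-unit floor
        for (i in which(isFailed)) {
            target <- stats::runif(1, 100, 400)
            sc <- target / max(meth[i, ], unmeth[i, ])
            meth[i, ] <- meth[i, ] * sc
            unmeth[i, ] <- unmeth[i, ] * sc
        }

        negCtrl <- matrix(abs(stats::rnorm(96 * nSamp, 0, bgScale)),
                          96, nSamp)

        ord <- genomicOrder(chrom, pos)
        manifest <- S4Vectors::DataFrame(
            probe_id = probeId[ord], chrom = chrom[ord], pos = pos[ord],
            gene = rep("", nTotal), region_label = rep("", nTotal),
            is_negative_control = rep(FALSE, nTotal))
        sampleSheet <- S4Vectors::DataFrame(sample_id = sampleIds,
                                            group = as.character(group))
        meth <- meth[ord, , drop = FALSE]
        unmeth <- unmeth[ord, , drop = FALSE]
        dimnames(meth) <- dimnames(unmeth) <- list(probeId[ord], sampleIds)

        truth <- S4Vectors::DataFrame(
            probe_id = probeId[ord], chrom = chrom[ord], pos = pos[ord],
            is_planted = (effect != 0)[ord], true_effect = effect[ord],
            dmr_id = dmrId[ord], is_failed = isFailed[ord],
            is_y = isY[ord], is_blacklisted = isBlack[ord])

        raw <- MethylRawSet(meth, unmeth, manifest, sampleSheet,
                            negativeControls = negCtrl)
        list(raw = raw, blacklist = sort(probeId[isBlack]),
             truth = truth)
    })
}

#' Realised effect sizes of planted probes
#'
#' Computes, for every planted probe in a simulation truth table, the
#' realised delta-beta (case group mean minus control group mean) in a beta
#' matrix, for checking that generated data carry the specified effects.
#'
#' @param beta a \linkS4class{MethylBetaSet}, or a numeric matrix
#'   (probes x samples) if \code{groups} is given.
#' @param truth the truth table from [simulateMethylation()].
#' @param groups factor of \code{"control"} / \code{"case"} per sample;
#'   taken from \code{beta} when it is a \linkS4class{MethylBetaSet}.
#' @return a [S4Vectors::DataFrame] with one row per planted probe present
#'   in \code{beta}: \code{probe_id}, \code{true_effect},
#'   \code{realised_effect}.
#' @export
empiricalEffect <- function(beta, truth, groups = NULL) {
    if (is(beta, "MethylBetaSet")) {
        groups <- sampleGroups(beta)
        mat <- getBeta(beta)
    } else {
        mat <- as.matrix(beta)
        if (is.null(groups)) stop("'groups' required for a plain matrix")
        groups <- factor(as.character(groups),
                         levels = c("control", "case"))
    }
    ids <- truth$probe_id[truth$is_planted]
    ids <- ids[ids %in% rownames(mat)]
    sub <- mat[ids, , drop = FALSE]
    realised <- rowMeans(sub[, groups == "case", drop = FALSE]) -
        rowMeans(sub[, groups == "control", drop = FALSE])
    S4Vectors::DataFrame(
        probe_id = ids,
        true_effect = truth$true_effect[match(ids, truth$probe_id)],
        realised_effect = unname(realised))
}

#' Write a simulated dataset to disk
#'
#' Emits the exact file formats the readers in this package consume:
#' \code{manifest.csv}, \code{sample_sheet.csv}, \code{meth.tsv},
#' \code{unmeth.tsv}, \code{negative_controls.tsv}, \code{blacklist.txt}
#' and \code{truth.csv}.
#'
#' @param sim result of [simulateMethylation()].
#' @param dir output directory (created if absent).
#' @return invisibly, a named character vector of the written paths.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    writeManifest(probeManifestWithControls(sim$raw), p("manifest.csv"))
    ss <- S4Vectors::DataFrame(
        sample_id = colnames(sim$raw),
        group = as.character(sampleGroups(sim$raw)))
    writeSampleSheet(ss, p("sample_sheet.csv"))
    writeMatrixTSV(getMeth(sim$raw), p("meth.tsv"))
    writeMatrixTSV(getUnmeth(sim$raw), p("unmeth.tsv"))
    nc <- negativeControls(sim$raw)
    rownames(nc) <- sprintf("neg_%03d", seq_len(nrow(nc)))
    writeMatrixTSV(nc, p("negative_controls.tsv"))
    writeBlacklist(sim$blacklist, p("blacklist.txt"))
    utils::write.csv(as.data.frame(sim$truth), p("truth.csv"),
                     row.names = FALSE, quote = FALSE)
    invisible(c(manifest = p("manifest.csv"),
                sample_sheet = p("sample_sheet.csv"),
                meth = p("meth.tsv"), unmeth = p("unmeth.tsv"),
                negative_controls = p("negative_controls.tsv"),
                blacklist = p("blacklist.txt"), truth = p("truth.csv")))
}

# manifest including the is_negative_control column expected on disk
probeManifestWithControls <- function(object) {
    man <- probeManifest(object)
    man$is_negative_control <- rep(FALSE, nrow(man))
    man
}
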