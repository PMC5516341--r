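#' Background-correct intensities with negative-control probes
#'
#' For each sample, subtracts the median of that sample's negative-control
#' (background) probe intensities from every entry of both channels, then
#' floors at 1 so downstream log/ratio operations stay defined.  This is a
#' deliberately simple, closed-form background model: negative-control
#' probes have no genomic target, so their median estimates optical and
#' hybridisation background per array.
#'
#' @param object a \linkS4class{MethylRawSet} carrying negative-control
#'   intensities (see [MethylRawSet()]).
#' @return a \linkS4class{MethylRawSet} with corrected channels; the
#'   negative-control matrix is dropped (it has been consumed).
#' @export
backgroundCorrect <- function(object) {
    stopifnot(is(object, "MethylRawSet"))
    nc <- negativeControls(object)
    if (is.null(nc) || nrow(nc) < 1L)
        stop("every sample needs at least one negative-control intensity")
    offset <- apply(nc, 2, stats::median)
    corr <- function(mat) pmax(sweep(mat, 2, offset, "-"), 1)
    SummarizedExperiment::assay(object, "Meth") <-
        corr(SummarizedExperiment::assay(object, "Meth"))
    SummarizedExperiment::assay(object, "Unmeth") <-
        corr(SummarizedExperiment::assay(object, "Unmeth"))
    metadata(object)$negativeControls <- NULL
    metadata(object)$backgroundOffset <- offset
    object
}

#' Quantile-normalise a matrix across columns
#'
#' Plain quantile normalisation: each column's sorted values are replaced
#' by the per-rank mean of all columns' sorted values, preserving each
#' column's original rank order, so that afterwards every column has the
#' identical multiset of values.  Ties within a column all receive the mean
#' of the rank means over the tied block, which makes the result invariant
#' to permutation of tied entries.
#'
#' @param mat numeric matrix with >= 2 columns and no missing values.
#' @return matrix of the same shape and dimnames.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantileNormalize <- function(mat) {
    mat <- as.matrix(mat)
    if (ncol(mat) < 2L) stop("quantile normalisation needs >= 2 columns")
    if (anyNA(mat)) stop("missing values are not supported")
    refe <- rowMeans(apply(mat, 2, sort, method = "quick"))
    out <- apply(mat, 2, function(x) {
        res <- numeric(length(x))
        res[order(x)] <- refe
        # tied entries all get the mean rank-mean over their tied block
        if (anyDuplicated(x)) res <- stats::ave(res, x, FUN = mean)
        res
    })
    dimnames(out) <- dimnames(mat)
    out
}

#' @describeIn quantileNormalize apply [quantileNormalize()] to each
#'   channel of a \linkS4class{MethylRawSet} independently.
#' @param object a \linkS4class{MethylRawSet}.
#' @export
quantileNormalizeChannels <- function(object) {
    stopifnot(is(object, "MethylRawSet"))
    SummarizedExperiment::assay(object, "Meth") <-
        quantileNormalize(SummarizedExperiment::assay(object, "Meth"))
    SummarizedExperiment::assay(object, "Unmeth") <-
        quantileNormalize(SummarizedExperiment::assay(object, "Unmeth"))
    object
}

#' Compute beta values
#'
#' The methylation fraction at each probe/sample is
#' \deqn{\beta = M / (M + U + \mathrm{offset})}
#' with the Illumina-convention offset of 100 intensity units stabilising
#' low-intensity probes; values lie in [0, 1) for offset > 0.
#'
#' @param meth,unmeth non-negative numeric matrices of equal shape, or a
#'   single \linkS4class{MethylRawSet} as \code{meth}.
#' @param offset non-negative stabilising constant (default 100).
#' @return a numeric matrix of betas, or a \linkS4class{MethylBetaSet} when
#'   called on a \linkS4class{MethylRawSet}.
#' @examples
#' computeBeta(matrix(4900), matrix(0))   # 0.98
#' @export
computeBeta <- function(meth, unmeth = NULL, offset = 100) {
    if (is(meth, "MethylRawSet")) {
        object <- meth
        b <- computeBeta(getMeth(object), getUnmeth(object), offset)
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = S4Vectors::SimpleList(Beta = b),
            rowData = SummarizedExperiment::rowData(object),
            colData = SummarizedExperiment::colData(object))
        return(new("MethylBetaSet", se))
    }
    if (offset < 0) stop("offset must be >= 0")
    if (!identical(dim(meth), dim(unmeth)))
        stop("'meth' and 'unmeth' must have identical shapes")
    if (min(meth) < 0 || min(unmeth) < 0)
        stop("negative intensities are not valid")
    denom <- meth + unmeth + offset
    b <- meth / denom
    b[denom == 0] <- 0
    b
}

#' Remove failed probes
#'
#' A probe has failed when, in every sample, both the methylated and the
#' unmethylated channel are below \code{threshold} intensity units (strict
#' \code{<}; a probe sitting exactly at the threshold is retained).  A
#' single sample with one channel at or above the threshold rescues the
#' probe.
#'
#' @param object a \linkS4class{MethylRawSet}.
#' @param threshold intensity floor in units (default 1000).
#' @return list with \code{object} (probes retained) and \code{removed}
#'   (character vector of failed probe ids).
#' @export
filterFailedProbes <- function(object, threshold = 1000) {
    m <- getMeth(object); u <- getUnmeth(object)
    failed <- rowSums(m >= threshold | u >= threshold) == 0L
    list(object = object[!failed, ], removed = rownames(object)[failed])
}

#' Remove Y-chromosome probes
#'
#' @param object a \linkS4class{MethylRawSet} or
#'   \linkS4class{MethylBetaSet}.
#' @return list with \code{object} and \code{removed} probe ids.
#' @export
filterYProbes <- function(object) {
    y <- SummarizedExperiment::rowData(object)$chrom == "Y"
    if (all(y)) warning("all probes are on chromosome Y; none retained")
    list(object = object[!y, ], removed = rownames(object)[y])
}

#' Remove blacklisted (e.g. multi-mapping) probes
#'
#' Blacklist entries absent from the object are ignored with a logged
#' count; cross-reactive probes are typically listed for a whole array,
#' not one experiment's probe subset.
#'
#' @param object a \linkS4class{MethylRawSet} or
#'   \linkS4class{MethylBetaSet}.
#' @param blacklist character vector of probe ids.
#' @return list with \code{object} and \code{removed} probe ids.
#' @export
filterBlacklist <- function(object, blacklist) {
    hit <- rownames(object) %in% blacklist
    absent <- length(setdiff(blacklist, rownames(object)))
    if (absent > 0)
        .msg(absent, " blacklist entr",
             if (absent == 1) "y is" else "ies are",
             " not on the array; ignored")
    list(object = object[!hit, ], removed = rownames(object)[hit])
}

#' Run the full preprocessing / QC pipeline
#'
#' Fixed stage order: background correction with negative controls,
#' per-channel quantile normalisation, failed-probe removal (both channels
#' below the intensity threshold in every sample), Y-chromosome removal,
#' blacklist removal, then beta-value computation.  Each probe is counted
#' against the first filter that removes it, so QC-report counts are
#' disjoint and additive.
#'
#' @param object a \linkS4class{MethylRawSet} with negative controls.
#' @param blacklist character vector of probe ids to exclude (may be
#'   empty).
#' @param intensityThreshold failed-probe intensity floor (units).
#' @param betaOffset offset for [computeBeta()].
#' @return list with \code{beta} (a \linkS4class{MethylBetaSet}) and
#'   \code{report} (a \linkS4class{QCReport}).
#' @examples
#' sim <- simulateMethylation(nCase = 3, nControl = 3, nNullProbes = 200,
#'                            seed = 11)
#' qc <- runQC(sim$raw, sim$blacklist)
#' qc$report
#' @export
runQC <- function(object, blacklist = character(),
                  intensityThreshold = 1000, betaOffset = 100) {
    stopifnot(is(object, "MethylRawSet"))
    nInput <- nrow(object)
    x <- backgroundCorrect(object)
    x <- quantileNormalizeChannels(x)
    f1 <- filterFailedProbes(x, intensityThreshold)
    f2 <- filterYProbes(f1$object)
    f3 <- filterBlacklist(f2$object, blacklist)
    beta <- computeBeta(f3$object, offset = betaOffset)
    report <- new("QCReport",
        nInput = as.integer(nInput),
        failedIds = f1$removed, yIds = f2$removed,
        blacklistIds = f3$removed,
        nRetained = as.integer(nrow(f3$object)))
    validObject(report)
    .msg("QC: ", nInput, " probes in; removed ",
         length(f1$removed), " failed, ", length(f2$removed), " chrY, ",
         length(f3$removed), " blacklisted; ", nrow(f3$object),
         " retained")
    list(beta = beta, report = report)
}

#' Write a QC report as CSV
#'
#' One row per filter with the probe count removed, plus input/retained
#' totals.
#'
#' @param report a \linkS4class{QCReport}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeQCReport <- function(report, path) {
    cc <- qcCounts(report)
    df <- data.frame(metric = names(cc), count = unname(cc))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
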