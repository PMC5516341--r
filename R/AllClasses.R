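#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' MethylRawSet: paired two-channel methylation intensities
#'
#' Container for raw (or corrected/normalised) Illumina 450K-style
#' intensities.  Extends \linkS4class{SummarizedExperiment} with two assays,
#' \code{Meth} and \code{Unmeth} (probes x samples, non-negative), a probe
#' manifest in \code{rowData} (\code{chrom}, \code{pos}, \code{gene},
#' \code{region_label}), a \code{group} factor (\code{"control"},
#' \code{"case"}) in \code{colData}, and a matrix of per-sample
#' negative-control intensities in \code{metadata(x)$negativeControls}.
#'
#' @seealso [MethylRawSet()] for the constructor, [runQC()] for the
#'   preprocessing pipeline that consumes it.
#' @export
setClass("MethylRawSet", contains = "SummarizedExperiment")

setValidity("MethylRawSet", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("Meth", "Unmeth") %in% an))
        msg <- c(msg, "assays 'Meth' and 'Unmeth' are required")
    else {
        m <- SummarizedExperiment::assay(object, "Meth")
        u <- SummarizedExperiment::assay(object, "Unmeth")
        if (anyNA(m) || anyNA(u))
            msg <- c(msg, "intensities must not contain NA")
        else if (min(m) < 0 || min(u) < 0)
            msg <- c(msg, "intensities must be non-negative")
    }
    rd <- SummarizedExperiment::rowData(object)
    need <- c("chrom", "pos")
    if (!all(need %in% colnames(rd)))
        msg <- c(msg, "rowData must contain columns 'chrom' and 'pos'")
    else {
        if (any(rd$pos < 1)) msg <- c(msg, "probe positions must be >= 1")
        if (any(!nzchar(as.character(rd$chrom))))
            msg <- c(msg, "chrom labels must be non-empty")
    }
    if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    else {
        g <- SummarizedExperiment::colData(object)$group
        if (!all(as.character(g) %in% c("case", "control")))
            msg <- c(msg, "group labels must be 'case' or 'control'")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "probe ids (rownames) must be unique")
    nc <- metadata(object)$negativeControls
    if (!is.null(nc)) {
        if (!is.matrix(nc) || ncol(nc) != ncol(object))
            msg <- c(msg, "negativeControls must be a matrix with one column per sample")
    }
    if (length(msg)) msg else TRUE
})

#' MethylBetaSet: methylation beta values
#'
#' Post-QC methylation fractions.  Extends
#' \linkS4class{SummarizedExperiment} with a single assay \code{Beta}
#' (probes x samples, values in [0, 1]); \code{rowData} and \code{colData}
#' carry the same annotation as the \linkS4class{MethylRawSet} it was
#' derived from.
#'
#' @export
setClass("MethylBetaSet", contains = "SummarizedExperiment")

setValidity("MethylBetaSet", function(object) {
    msg <- character()
    if (!"Beta" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'Beta' is required")
    else {
        b <- SummarizedExperiment::assay(object, "Beta")
        if (anyNA(b)) msg <- c(msg, "beta values must not contain NA")
        else if (min(b) < 0 || max(b) > 1)
            msg <- c(msg, "beta values must lie in [0, 1]")
    }
    if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    if (length(msg)) msg else TRUE
})

#' QCReport: probe-filtering bookkeeping
#'
#' Records, for one [runQC()] invocation, how many probes entered, how many
#' were removed by each filter (failed-intensity, Y chromosome,
#' cross-reactive blacklist, applied in that fixed order so removal sets
#' are disjoint), which probe ids each filter removed, and how many probes
#' were retained.
#'
#' @slot nInput number of probes before filtering.
#' @slot failedIds,yIds,blacklistIds character vectors of removed probe ids,
#'   one per filter, disjoint.
#' @slot nRetained number of probes surviving all filters.
#' @export
setClass("QCReport",
    representation(
        nInput = "integer",
        failedIds = "character",
        yIds = "character",
        blacklistIds = "character",
        nRetained = "integer"
    )
)

setValidity("QCReport", function(object) {
    removed <- c(object@failedIds, object@yIds, object@blacklistIds)
    if (anyDuplicated(removed))
        return("filter removal sets must be disjoint")
    if (object@nInput - length(removed) != object@nRetained)
        return("nInput - removals must equal nRetained")
    TRUE
})
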