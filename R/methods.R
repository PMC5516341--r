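#' Construct a MethylRawSet
#'
#' Assemble paired intensity matrices, a probe manifest, a sample sheet and
#' (optionally) negative-control intensities into a validated
#' \linkS4class{MethylRawSet}.  Row and column labels of the matrices must
#' match the manifest probe ids and sample-sheet sample ids exactly (order
#' included); mismatches are an error rather than silently reordered.
#'
#' @param meth,unmeth numeric matrices (probes x samples), non-negative,
#'   with probe ids as rownames and sample ids as colnames.
#' @param manifest a data.frame/DataFrame of probe records with columns
#'   \code{probe_id}, \code{chrom}, \code{pos}, \code{gene},
#'   \code{region_label}, \code{is_negative_control} (see [readManifest()]).
#' @param sampleSheet a data.frame/DataFrame with columns \code{sample_id}
#'   and \code{group} (values \code{"case"} / \code{"control"}).
#' @param negativeControls optional numeric matrix of background (negative
#'   control) probe intensities, one column per sample.
#' @return a \linkS4class{MethylRawSet}.
#' @examples
#' m <- matrix(c(5000, 200), 1, 2, dimnames = list("cg1", c("s1", "s2")))
#' man <- data.frame(probe_id = "cg1", chrom = "1", pos = 100L,
#'                   gene = "", region_label = "", is_negative_control = FALSE)
#' ss <- data.frame(sample_id = c("s1", "s2"),
#'                  group = c("case", "control"))
#' MethylRawSet(m, m, man, ss)
#' @export
MethylRawSet <- function(meth, unmeth, manifest, sampleSheet,
                         negativeControls = NULL) {
    if (!identical(dim(meth), dim(unmeth)))
        stop("'meth' and 'unmeth' must have identical dimensions")
    if (!identical(rownames(meth), as.character(manifest$probe_id)))
        stop("matrix rownames must match manifest probe_id order exactly")
    if (!identical(colnames(meth), as.character(sampleSheet$sample_id)))
        stop("matrix colnames must match sample sheet sample_id order exactly")
    cd <- S4Vectors::DataFrame(
        group = factor(as.character(sampleSheet$group),
                       levels = c("control", "case")),
        row.names = as.character(sampleSheet$sample_id))
    rd <- S4Vectors::DataFrame(
        chrom = as.character(manifest$chrom),
        pos = as.integer(manifest$pos),
        gene = as.character(manifest$gene),
        region_label = as.character(manifest$region_label),
        row.names = as.character(manifest$probe_id))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(Meth = meth, Unmeth = unmeth),
        rowData = rd, colData = cd)
    obj <- new("MethylRawSet", se)
    if (!is.null(negativeControls)) {
        negativeControls <- as.matrix(negativeControls)
        colnames(negativeControls) <- colnames(meth)
        metadata(obj)$negativeControls <- negativeControls
    }
    validObject(obj)
    obj
}

#' @rdname MethylRawSet-class
#' @aliases getMeth,MethylRawSet-method
#' @exportMethod getMeth
setMethod("getMeth", "MethylRawSet", function(object)
    SummarizedExperiment::assay(object, "Meth"))

#' @rdname MethylRawSet-class
#' @exportMethod getUnmeth
setMethod("getUnmeth", "MethylRawSet", function(object)
    SummarizedExperiment::assay(object, "Unmeth"))

#' @rdname MethylBetaSet-class
#' @exportMethod getBeta
setMethod("getBeta", "MethylBetaSet", function(object)
    SummarizedExperiment::assay(object, "Beta"))

#' @rdname MethylRawSet-class
#' @exportMethod negativeControls
setMethod("negativeControls", "MethylRawSet", function(object)
    metadata(object)$negativeControls)

.sampleGroups <- function(object) {
    g <- SummarizedExperiment::colData(object)$group
    factor(as.character(g), levels = c("control", "case"))
}

#' @rdname MethylRawSet-class
#' @exportMethod sampleGroups
setMethod("sampleGroups", "MethylRawSet", .sampleGroups)

#' @rdname MethylBetaSet-class
#' @exportMethod sampleGroups
setMethod("sampleGroups", "MethylBetaSet", .sampleGroups)

.probeManifest <- function(object) {
    rd <- SummarizedExperiment::rowData(object)
    S4Vectors::DataFrame(probe_id = rownames(object), rd)
}

#' @rdname MethylRawSet-class
#' @exportMethod probeManifest
setMethod("probeManifest", "MethylRawSet", .probeManifest)

#' @rdname MethylBetaSet-class
#' @exportMethod probeManifest
setMethod("probeManifest", "MethylBetaSet", .probeManifest)

setMethod("show", "MethylRawSet", function(object) {
    g <- .sampleGroups(object)
    cat("MethylRawSet with", nrow(object), "probes and",
        ncol(object), "samples\n")
    cat("  groups:", sum(g == "case"), "case /",
        sum(g == "control"), "control\n")
    nc <- metadata(object)$negativeControls
    cat("  negative controls per sample:",
        if (is.null(nc)) 0L else nrow(nc), "\n")
})

setMethod("show", "MethylBetaSet", function(object) {
    g <- .sampleGroups(object)
    b <- SummarizedExperiment::assay(object, "Beta")
    cat("MethylBetaSet with", nrow(object), "probes and",
        ncol(object), "samples\n")
    cat("  groups:", sum(g == "case"), "case /",
        sum(g == "control"), "control\n")
    cat(sprintf("  beta range: [%.3f, %.3f]\n", min(b), max(b)))
})

#' @describeIn QCReport-class accessor returning the per-filter removal
#'   counts and retained count as a named integer vector.
#' @param object a \linkS4class{QCReport}.
#' @export
qcCounts <- function(object) {
    stopifnot(is(object, "QCReport"))
    c(n_input = object@nInput,
      n_failed_removed = length(object@failedIds),
      n_y_removed = length(object@yIds),
      n_blacklist_removed = length(object@blacklistIds),
      n_retained = object@nRetained)
}

#' @describeIn QCReport-class accessor returning the removed probe ids as a
#'   named list with elements \code{failed}, \code{y}, \code{blacklist}.
#' @export
qcRemovedIds <- function(object) {
    stopifnot(is(object, "QCReport"))
    list(failed = object@failedIds, y = object@yIds,
         blacklist = object@blacklistIds)
}

setMethod("show", "QCReport", function(object) {
    cc <- qcCounts(object)
    cat("QCReport\n")
    cat("  probes in:            ", cc[["n_input"]], "\n")
    cat("  failed-intensity out: ", cc[["n_failed_removed"]], "\n")
    cat("  Y-chromosome out:     ", cc[["n_y_removed"]], "\n")
    cat("  blacklist out:        ", cc[["n_blacklist_removed"]], "\n")
    cat("  retained:             ", cc[["n_retained"]], "\n")
})
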