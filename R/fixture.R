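#' Reference DMP set: CD4+ T-cell methylation in relapsing-remitting MS
#'
#' A packaged set of 33 differentially methylated CpG positions reported in
#' a published epigenome-wide study of CD4+ T cells from treatment-naive
#' female relapsing-remitting multiple sclerosis patients (28 cases) versus
#' age-matched healthy controls (22), on the Illumina 450K platform.  The
#' 33 CpGs form six regional clusters (DMRs) at \emph{PM20D1} (chr1),
#' \emph{HCG4P6}, \emph{RNF39}, \emph{HLA-DRB5} and \emph{HLA-DRB1} (all in
#' the chr6 MHC region) and \emph{ERICH1} (chr8), and are the canonical
#' regression target for the DMR caller: feeding them to [callDMRs()] with
#' default parameters reproduces the six published regions.
#'
#' Each record carries the published per-CpG one-way ANOVA F statistic,
#' p-value, control and case group mean beta values, and delta-beta
#' (case mean minus control mean).  P-values that the source reports only
#' to three decimals as \code{0.000} are stored as \code{0.0005} with
#' \code{p_truncated = TRUE}; downstream code must not treat those four
#' entries as measured values.
#'
#' @return a [S4Vectors::DataFrame] with 33 rows and columns
#'   \code{probe_id}, \code{chrom}, \code{pos} (1-based bp, hg19),
#'   \code{dmr_index} (1-6, genomic order), \code{gene},
#'   \code{region_label}, \code{F_stat}, \code{p_value}, \code{p_truncated},
#'   \code{mean_control}, \code{mean_case}, \code{delta_beta}.
#' @examples
#' dmps <- rrmsReferenceDMPs()
#' table(dmps$gene)
#' dmrs <- callDMRs(dmps)
#' @export
rrmsReferenceDMPs <- function() {
    path <- system.file("extdata", "rrms_cd4_reference_dmps.csv",
                        package = "methylDMR", mustWork = TRUE)
    df <- utils::read.csv(path, colClasses = c(
        probe_id = "character", chrom = "character", pos = "integer",
        dmr_index = "integer", gene = "character",
        region_label = "character", F_stat = "numeric",
        p_value = "numeric", p_truncated = "logical",
        mean_control = "numeric", mean_case = "numeric",
        delta_beta = "numeric"))
    S4Vectors::DataFrame(df)
}

#' @describeIn rrmsReferenceDMPs probe manifest for the same 33 CpGs, in
#'   the layout [readManifest()] produces (no negative-control probes).
#' @export
rrmsReferenceManifest <- function() {
    d <- rrmsReferenceDMPs()
    S4Vectors::DataFrame(
        probe_id = d$probe_id, chrom = d$chrom, pos = d$pos,
        gene = d$gene, region_label = d$region_label,
        is_negative_control = rep(FALSE, nrow(d)))
}
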