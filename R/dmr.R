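#' Chain prioritised DMPs into differentially methylated regions
#'
#' Sorts records genomically, then greedily extends a run while the next
#' CpG is on the same chromosome, at most \code{maxGap} bp downstream of
#' the previous CpG (inclusive), and methylated in the same direction
#' (sign of delta-beta) as the run.  A violation of any condition closes
#' the run and opens a new one at the offending CpG.  Runs with at least
#' \code{minCpgs} members are emitted as DMRs, numbered in genomic order.
#' Because the chaining constraints are purely local (consecutive-pair
#' gap and shared sign), the greedy scan returns exactly the maximal valid
#' runs.
#'
#' Adjacency is defined over the supplied (prioritised) CpGs only:
#' intervening sub-threshold array probes do not interrupt a region.
#'
#' @param dmps DataFrame/data.frame of prioritised DMP records with at
#'   least \code{probe_id}, \code{chrom}, \code{pos}, \code{delta_beta}
#'   (non-zero), and optionally \code{gene}.
#' @param maxGap maximum distance in bp between consecutive member CpGs
#'   (inclusive; default 1000).
#' @param minCpgs minimum CpGs per region (default 2).
#' @return a [GenomicRanges::GRanges], one range per DMR spanning the
#'   first to last member CpG (1-based inclusive), with metadata columns
#'   \code{dmr_id}, \code{n_cpgs}, \code{span_bp}, \code{direction}
#'   (\code{"hyper"}/\code{"hypo"}), \code{mean_delta_beta},
#'   \code{max_abs_delta_beta}, \code{gene_labels} (CharacterList of
#'   sorted unique non-empty labels) and \code{probe_ids} (CharacterList
#'   in positional order).
#' @examples
#' dmrs <- callDMRs(rrmsReferenceDMPs())
#' dmrs$n_cpgs       # 6 3 11 3 7 3
#' @export
callDMRs <- function(dmps, maxGap = 1000, minCpgs = 2) {
    df <- as.data.frame(dmps)
    if (nrow(df) == 0L) return(.emptyDmrGRanges())
    if (any(df$delta_beta == 0))
        stop("delta_beta must be non-zero for all prioritised records")
    dup <- duplicated(df[, c("chrom", "pos")]) |
        duplicated(df[, c("chrom", "pos")], fromLast = TRUE)
    if (any(dup))
        stop("duplicate (chrom, pos): ",
             paste(df$probe_id[dup], collapse = ", "))
    df <- df[genomicOrder(df$chrom, df$pos), , drop = FALSE]
    n <- nrow(df)
    sameRun <- c(FALSE,
        df$chrom[-1] == df$chrom[-n] &
        (df$pos[-1] - df$pos[-n]) <= maxGap &
        sign(df$delta_beta[-1]) == sign(df$delta_beta[-n]))
    runId <- cumsum(!sameRun)
    runs <- split(seq_len(n), runId)
    runs <- runs[lengths(runs) >= minCpgs]
    if (!length(runs)) return(.emptyDmrGRanges())
    lv <- unique(df$chrom)   # already genomically sorted
    recs <- lapply(runs, function(idx)
        summarizeDMR(df[idx, , drop = FALSE], chromLevels = lv))
    gr <- do.call(c, unname(recs))
    gr$dmr_id <- seq_along(gr)
    gr
}

#' Summarise one run of sign-consistent CpGs as a DMR record
#'
#' @param run data.frame of member DMP records, position-sorted, all on
#'   one chromosome with a shared delta-beta sign.
#' @param chromLevels optional chromosome level set for the result's
#'   seqinfo (used by [callDMRs()] so per-run records combine cleanly).
#' @return a length-1 [GenomicRanges::GRanges] (see [callDMRs()]).
#' @export
summarizeDMR <- function(run, chromLevels = NULL) {
    run <- as.data.frame(run)
    stopifnot(nrow(run) >= 2L, length(unique(run$chrom)) == 1L,
              !is.unsorted(run$pos, strictly = TRUE))
    s <- sign(run$delta_beta)
    stopifnot(length(unique(s)) == 1L, all(s != 0))
    genes <- character(0)
    if (!is.null(run$gene)) genes <- sort(unique(run$gene[nzchar(run$gene)]))
    if (is.null(chromLevels)) chromLevels <- run$chrom[1]
    gr <- GenomicRanges::GRanges(
        seqnames = factor(run$chrom[1], levels = chromLevels),
        ranges = IRanges::IRanges(start = min(run$pos), end = max(run$pos)))
    gr$dmr_id <- NA_integer_
    gr$n_cpgs <- nrow(run)
    gr$span_bp <- max(run$pos) - min(run$pos)
    gr$direction <- if (s[1] > 0) "hyper" else "hypo"
    gr$mean_delta_beta <- mean(run$delta_beta)
    gr$max_abs_delta_beta <- max(abs(run$delta_beta))
    gr$gene_labels <- IRanges::CharacterList(list(genes))
    gr$probe_ids <- IRanges::CharacterList(list(run$probe_id))
    gr
}

.emptyDmrGRanges <- function() {
    gr <- GenomicRanges::GRanges()
    gr$dmr_id <- integer(0)
    gr$n_cpgs <- integer(0)
    gr$span_bp <- integer(0)
    gr$direction <- character(0)
    gr$mean_delta_beta <- numeric(0)
    gr$max_abs_delta_beta <- numeric(0)
    gr$gene_labels <- IRanges::CharacterList()
    gr$probe_ids <- IRanges::CharacterList()
    gr
}

#' Flatten a DMR GRanges into a plain table
#'
#' @param dmrs a [GenomicRanges::GRanges] from [callDMRs()].
#' @return data.frame with one row per DMR (gene labels and probe ids
#'   collapsed with \code{";"}).
#' @export
dmrTable <- function(dmrs) {
    data.frame(
        dmr_id = dmrs$dmr_id,
        chrom = as.character(GenomicRanges::seqnames(dmrs)),
        start_pos = GenomicRanges::start(dmrs),
        end_pos = GenomicRanges::end(dmrs),
        n_cpgs = dmrs$n_cpgs,
        span_bp = dmrs$span_bp,
        direction = dmrs$direction,
        mean_delta_beta = round(dmrs$mean_delta_beta, 4),
        max_abs_delta_beta = round(dmrs$max_abs_delta_beta, 4),
        genes = vapply(dmrs$gene_labels, paste, character(1),
                       collapse = ";"),
        probe_ids = vapply(dmrs$probe_ids, paste, character(1),
                           collapse = ";"))
}
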