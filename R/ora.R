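#' Hypergeometric upper-tail probability
#'
#' \eqn{P(X \ge k)} for \eqn{X} hypergeometric: the chance of drawing at
#' least \code{k} annotated genes when \code{n} genes are drawn without
#' replacement from a universe of \code{N} genes of which \code{K} are
#' annotated.  Equivalent to a one-sided Fisher exact test on the 2x2
#' overlap table.
#'
#' @param k observed overlap (0 <= k <= min(K, n)).
#' @param K genes in the set (within the universe).
#' @param n genes in the query list.
#' @param N universe size.
#' @return the upper-tail probability in (0, 1].
#' @examples
#' hypergeomUpperTail(4, 5, 4, 10)   # 5/210
#' @export
hypergeomUpperTail <- function(k, K, n, N) {
    if (any(K > N) || any(n > N) || any(k > pmin(K, n)) || any(k < 0))
        stop("inconsistent hypergeometric arguments")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, in input
#' order.  Thin wrapper over \code{p.adjust(method = "BH")} with input
#' validation; adjusted values are never smaller than the raw ones.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted values, same length and order.
#' @export
bhFDR <- function(p) {
    if (length(p) && (any(p <= 0) || any(p > 1) || anyNA(p)))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Tests each gene set for enrichment in a query gene list via the
#' one-sided hypergeometric test, with BH-FDR across sets.  Gene sets are
#' intersected with the universe first; query genes outside the universe
#' are dropped with a logged count.  A gene counts once however many CpGs
#' map to it — build the list and universe at the gene level (e.g. unique
#' gene symbols on the post-QC probe set).
#'
#' @param geneList character vector of query gene symbols.
#' @param geneSets named list of character vectors (see [readGMT()]).
#' @param universe character vector of all eligible gene symbols.
#' @param fdrThreshold significance cutoff on the adjusted values
#'   (default 0.05).
#' @return a [S4Vectors::DataFrame] sorted by p-value, one row per gene
#'   set with non-empty intersection with the universe: \code{set_id},
#'   \code{overlap}, \code{set_size_in_universe}, \code{list_size},
#'   \code{universe_size}, \code{expected_overlap}, \code{p_value},
#'   \code{fdr}, \code{significant}.
#' @export
runORA <- function(geneList, geneSets, universe, fdrThreshold = 0.05) {
    universe <- unique(universe)
    if (!length(universe)) stop("the gene universe is empty")
    geneList <- unique(geneList)
    outside <- setdiff(geneList, universe)
    if (length(outside))
        .msg(length(outside),
             " query gene(s) not in the universe; dropped")
    geneList <- intersect(geneList, universe)
    sets <- lapply(geneSets, intersect, universe)
    keep <- lengths(sets) > 0L
    sets <- sets[keep]
    N <- length(universe); n <- length(geneList)
    K <- lengths(sets)
    k <- vapply(sets, function(s) length(intersect(s, geneList)),
                integer(1))
    p <- hypergeomUpperTail(k, K, n, N)
    out <- S4Vectors::DataFrame(
        set_id = names(sets), overlap = unname(k),
        set_size_in_universe = unname(K),
        list_size = n, universe_size = N,
        expected_overlap = unname(n * K / N),
        p_value = unname(p), fdr = unname(bhFDR(p)))
    out$significant <- out$fdr < fdrThreshold
    out[order(out$p_value, out$set_id), ]
}

#' Write an ORA result table as CSV
#'
#' @param ora a DataFrame from [runORA()].
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeORATable <- function(ora, path) {
    utils::write.csv(as.data.frame(ora), path, row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}
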