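#' Read a probe manifest
#'
#' Parses a CSV probe manifest with one row per array probe.  Required
#' columns: \code{probe_id}, \code{chrom} (bare labels, e.g. \code{"1"},
#' \code{"X"}), \code{pos} (1-based bp), \code{gene}, \code{region_label}
#' (e.g. \code{"Body"}, \code{"TSS200"}), \code{is_negative_control}.
#' Row order is preserved.
#'
#' @param path CSV file path.
#' @return a [S4Vectors::DataFrame] of probe records in file order.
#' @export
readManifest <- function(path) {
    df <- utils::read.csv(path, colClasses = "character")
    need <- c("probe_id", "chrom", "pos", "gene", "region_label",
              "is_negative_control")
    missing <- setdiff(need, colnames(df))
    if (length(missing))
        stop("manifest is missing column(s): ",
             paste(missing, collapse = ", "))
    dup <- df$probe_id[duplicated(df$probe_id)]
    if (length(dup))
        stop("duplicate probe_id in manifest: ",
             paste(unique(dup), collapse = ", "))
    pos <- as.integer(df$pos)
    if (anyNA(pos) || any(pos < 1))
        stop("manifest 'pos' must be integers >= 1")
    if (any(!nzchar(df$chrom)))
        stop("manifest 'chrom' must be non-empty")
    S4Vectors::DataFrame(
        probe_id = df$probe_id, chrom = df$chrom, pos = pos,
        gene = df$gene, region_label = df$region_label,
        is_negative_control = as.logical(df$is_negative_control))
}

#' Write a probe manifest
#'
#' @param manifest a data.frame/DataFrame as returned by [readManifest()].
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeManifest <- function(manifest, path) {
    utils::write.csv(as.data.frame(manifest), path, row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}

#' Read / write a sample sheet
#'
#' A sample sheet is a CSV with columns \code{sample_id} (unique) and
#' \code{group} (\code{"case"} or \code{"control"}).
#'
#' @param path CSV file path.
#' @return [readSampleSheet()]: a [S4Vectors::DataFrame] in file order.
#' @export
readSampleSheet <- function(path) {
    df <- utils::read.csv(path, colClasses = "character")
    if (!all(c("sample_id", "group") %in% colnames(df)))
        stop("sample sheet needs columns 'sample_id' and 'group'")
    dup <- df$sample_id[duplicated(df$sample_id)]
    if (length(dup))
        stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
    bad <- setdiff(unique(df$group), c("case", "control"))
    if (length(bad))
        stop("group must be 'case' or 'control'; found: ",
             paste(bad, collapse = ", "))
    S4Vectors::DataFrame(sample_id = df$sample_id, group = df$group)
}

#' @rdname readSampleSheet
#' @param sampleSheet a data.frame/DataFrame with \code{sample_id}, \code{group}.
#' @export
writeSampleSheet <- function(sampleSheet, path) {
    utils::write.csv(as.data.frame(sampleSheet), path, row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}

#' Read / write an intensity (or beta) matrix as TSV
#'
#' On-disk matrix interchange format: TSV with probe ids in the first
#' column (header \code{probe_id}) and sample ids as the remaining column
#' headers.  Values are written with 6 significant digits, which bounds the
#' round-trip error of [writeMatrixTSV()] followed by [readMatrixTSV()].
#'
#' @param path TSV file path.
#' @return [readMatrixTSV()]: a numeric matrix with dimnames.
#' @export
readMatrixTSV <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = c(probe_id = "character"))
    if (colnames(df)[1] != "probe_id")
        stop("matrix TSV must have 'probe_id' as its first column")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$probe_id
    storage.mode(m) <- "double"
    m
}

#' @rdname readMatrixTSV
#' @param mat numeric matrix with probe-id rownames and sample-id colnames.
#' @export
writeMatrixTSV <- function(mat, path) {
    df <- data.frame(probe_id = rownames(mat),
                     signif(mat, 6), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' Read a probe blacklist
#'
#' One probe id per line (e.g. probes whose 50-mer aligns to multiple
#' genomic locations).  Blank lines and leading/trailing whitespace are
#' dropped.
#'
#' @param path text file path.
#' @return character vector of probe ids.
#' @export
readBlacklist <- function(path) {
    x <- trimws(readLines(path))
    unique(x[nzchar(x)])
}

#' @rdname readBlacklist
#' @param ids character vector of probe ids.
#' @export
writeBlacklist <- function(ids, path) {
    writeLines(ids, path)
    invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one gene set per line, tab-separated fields
#' \code{set_id}, \code{description}, then one or more gene symbols.
#' Duplicate genes within a line are collapsed.
#'
#' @param path GMT file path.
#' @return a named list of gene sets; each element is a character vector of
#'   unique gene symbols carrying a \code{description} attribute.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    sets <- vector("list", length(lines))
    ids <- character(length(lines))
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3)
            stop("GMT line ", i, " has fewer than 3 tab-separated fields")
        genes <- unique(f[-(1:2)])
        genes <- genes[nzchar(genes)]
        if (!length(genes))
            stop("GMT line ", i, " lists no genes")
        attr(genes, "description") <- f[2]
        sets[[i]] <- genes
        ids[i] <- f[1]
    }
    if (anyDuplicated(ids))
        stop("duplicate set_id in GMT: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    names(sets) <- ids
    sets
}

#' Export DMRs as a BED6 track
#'
#' Converts the 1-based inclusive CpG coordinates of each DMR to 0-based
#' half-open BED intervals (start = first CpG position - 1, end = last CpG
#' position).  The BED name is the DMR's primary gene label, the score is
#' \code{round(1000 * |mean delta-beta|)} capped at 1000, and the strand is
#' \code{"."}.  Chromosome names are emitted UCSC-style with a \code{"chr"}
#' prefix.
#'
#' @param dmrs a [GenomicRanges::GRanges] as returned by [callDMRs()]
#'   (may be empty).
#' @param path output BED path.
#' @return invisibly, \code{path}.
#' @export
writeDmrBed <- function(dmrs, path) {
    if (length(dmrs) == 0L) {
        cat("", file = path)
        return(invisible(path))
    }
    genes <- vapply(S4Vectors::mcols(dmrs)$gene_labels, function(g)
        if (length(g)) g[[1]] else ".", character(1))
    genes[!nzchar(genes)] <- "."
    score <- pmin(1000L,
        as.integer(round(1000 * abs(S4Vectors::mcols(dmrs)$mean_delta_beta))))
    bed <- data.frame(
        chrom = paste0("chr", as.character(GenomicRanges::seqnames(dmrs))),
        start = GenomicRanges::start(dmrs) - 1L,
        end = GenomicRanges::end(dmrs),
        name = genes,
        score = score,
        strand = ".")
    utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write a DMP result table as CSV
#'
#' Column layout mirrors the conventional published DMP table: CpG id,
#' chromosome, position, gene, gene region, F statistic, p-value, control
#' and case group mean betas, and delta-beta.
#'
#' @param dmps a DataFrame/data.frame of DMP records from [findDMPs()] or
#'   [prioritizeDMPs()].
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeDmpTable <- function(dmps, path) {
    df <- as.data.frame(dmps)
    out <- data.frame(
        `CpG ID` = df$probe_id, Chr = df$chrom, `Pos (bp)` = df$pos,
        Gene = df$gene, Region = df$region_label,
        `F stat` = signif(df$F_stat, 4), `P value` = signif(df$p_value, 4),
        Control = round(df$mean_control, 3), Case = round(df$mean_case, 3),
        `Delta beta` = round(df$delta_beta, 3), check.names = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write a DMR result table as CSV
#'
#' @param dmrs a [GenomicRanges::GRanges] from [callDMRs()].
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeDmrTable <- function(dmrs, path) {
    utils::write.csv(dmrTable(dmrs), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
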