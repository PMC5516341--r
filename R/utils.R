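# Genomic sort key for bare chromosome labels: 1..22 numeric, then X, Y, MT,
# then anything else alphabetically.
chromRank <- function(chrom) {
    chrom <- as.character(chrom)
    n <- suppressWarnings(as.integer(chrom))
    r <- ifelse(!is.na(n), n,
        ifelse(chrom == "X", 23L,
        ifelse(chrom == "Y", 24L,
        ifelse(chrom %in% c("M", "MT"), 25L, NA_integer_))))
    other <- is.na(r)
    if (any(other))
        r[other] <- 25L + match(chrom[other], sort(unique(chrom[other])))
    r
}

genomicOrder <- function(chrom, pos) order(chromRank(chrom), pos)

.msg <- function(...) message("[methylDMR] ", ...)
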