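#' Assemble a pipeline configuration
#'
#' Collects every input path and threshold of the end-to-end analysis in
#' one validated list.  \code{file} may name a YAML or JSON configuration;
#' arguments given directly override file values.  Thresholds default to
#' the published prioritisation constants: nominal p < 0.05, |delta-beta|
#' >= 0.1, CpG gap <= 1000 bp, >= 2 CpGs per region, 1000-unit failed-probe
#' intensity floor, beta offset 100, ORA FDR 5\%.
#'
#' @param file optional YAML/JSON config path.
#' @param ... fields to set/override: \code{manifest}, \code{meth},
#'   \code{unmeth}, \code{sample_sheet}, \code{negative_controls},
#'   \code{blacklist}, \code{gene_sets}, \code{output_dir},
#'   \code{p_threshold}, \code{delta_threshold}, \code{max_gap},
#'   \code{min_cpgs}, \code{intensity_threshold}, \code{beta_offset},
#'   \code{fdr_threshold}, \code{skip_ora}, \code{emit_bed}, \code{seed}.
#' @return a named list of class \code{"methylDMRConfig"}.
#' @export
pipelineConfig <- function(file = NULL, ...) {
    cfg <- list(
        manifest = NULL, meth = NULL, unmeth = NULL, sample_sheet = NULL,
        negative_controls = NULL, blacklist = NULL, gene_sets = NULL,
        output_dir = ".",
        p_threshold = 0.05, delta_threshold = 0.1,
        max_gap = 1000, min_cpgs = 2,
        intensity_threshold = 1000, beta_offset = 100,
        fdr_threshold = 0.05,
        skip_ora = FALSE, emit_bed = TRUE, seed = 1L)
    if (!is.null(file)) {
        parsed <- if (grepl("\\.json$", file, ignore.case = TRUE))
            jsonlite::read_json(file, simplifyVector = TRUE)
        else yaml::read_yaml(file)
        unknown <- setdiff(names(parsed), names(cfg))
        if (length(unknown))
            stop("unknown config field(s): ",
                 paste(unknown, collapse = ", "))
        cfg[names(parsed)] <- parsed
    }
    dots <- list(...)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
    num <- c("p_threshold", "delta_threshold", "max_gap", "min_cpgs",
             "intensity_threshold", "beta_offset", "fdr_threshold")
    for (f in num)
        if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
            stop("config field '", f, "' must be a non-negative number")
    class(cfg) <- "methylDMRConfig"
    cfg
}

#' Run the full differential-methylation pipeline
#'
#' Reads all inputs named in the configuration, runs QC
#' ([runQC()]), per-CpG testing ([findDMPs()]), prioritisation
#' ([prioritizeDMPs()]), region calling ([callDMRs()]) and, when a gene-set
#' GMT is configured, over-representation analysis ([runORA()]) with the
#' gene universe taken as all unique non-empty gene symbols on the post-QC
#' probe set.  Writes \code{qc_report.csv}, \code{dmp_table.csv},
#' \code{dmr_table.csv}, optionally \code{dmr.bed} and
#' \code{ora_table.csv}, and a \code{run_manifest.json} with input file
#' digests (recorded before processing), stage row counts and the
#' package version.  Identical configuration and inputs produce identical
#' result tables.
#'
#' @param config a list from [pipelineConfig()].
#' @return invisibly, a list with \code{qc}, \code{dmps},
#'   \code{prioritized}, \code{dmrs}, \code{ora} (NULL when skipped) and
#'   \code{run_manifest}.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "methylDMRConfig"))
    need <- c("manifest", "meth", "unmeth", "sample_sheet",
              "negative_controls")
    for (f in need)
        if (is.null(config[[f]]))
            stop("pipeline config is missing required input '", f, "'")
    inputs <- unlist(config[c(need, "blacklist", "gene_sets")])
    missing <- inputs[!file.exists(inputs)]
    if (length(missing))
        stop("input file(s) not found: ", paste(missing, collapse = ", "))
    digests <- as.list(tools::md5sum(inputs))

    outDir <- config$output_dir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    .msg("stage qc: reading inputs")
    manifest <- readManifest(config$manifest)
    sampleSheet <- readSampleSheet(config$sample_sheet)
    meth <- readMatrixTSV(config$meth)
    unmeth <- readMatrixTSV(config$unmeth)
    negCtrl <- readMatrixTSV(config$negative_controls)
    blacklist <- if (is.null(config$blacklist)) character()
        else readBlacklist(config$blacklist)
    raw <- MethylRawSet(meth, unmeth, manifest, sampleSheet,
                        negativeControls = negCtrl)
    qc <- runQC(raw, blacklist,
                intensityThreshold = config$intensity_threshold,
                betaOffset = config$beta_offset)
    writeQCReport(qc$report, file.path(outDir, "qc_report.csv"))

    .msg("stage dmp: testing ", nrow(qc$beta), " probes")
    dmps <- findDMPs(qc$beta)
    prior <- prioritizeDMPs(dmps, config$p_threshold,
                            config$delta_threshold)
    writeDmpTable(prior, file.path(outDir, "dmp_table.csv"))
    .msg("stage dmp: ", nrow(prior), " DMPs pass p < ",
         config$p_threshold, ", |delta-beta| >= ", config$delta_threshold)

    .msg("stage dmr: chaining")
    dmrs <- callDMRs(prior, maxGap = config$max_gap,
                     minCpgs = config$min_cpgs)
    writeDmrTable(dmrs, file.path(outDir, "dmr_table.csv"))
    if (isTRUE(config$emit_bed))
        writeDmrBed(dmrs, file.path(outDir, "dmr.bed"))
    .msg("stage dmr: ", length(dmrs), " DMRs")

    ora <- NULL
    if (!isTRUE(config$skip_ora) && !is.null(config$gene_sets)) {
        .msg("stage ora")
        geneSets <- readGMT(config$gene_sets)
        man <- probeManifest(qc$beta)
        universe <- unique(man$gene[nzchar(man$gene)])
        geneList <- unique(prior$gene[nzchar(prior$gene)])
        ora <- runORA(geneList, geneSets, universe,
                      fdrThreshold = config$fdr_threshold)
        writeORATable(ora, file.path(outDir, "ora_table.csv"))
    }

    runManifest <- list(
        package = "methylDMR",
        version = as.character(utils::packageVersion("methylDMR")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        config = unclass(config)[!vapply(config, is.null, logical(1))],
        input_digests = digests,
        counts = list(
            probes_in = unname(qcCounts(qc$report)[["n_input"]]),
            probes_retained = unname(qcCounts(qc$report)[["n_retained"]]),
            dmps_tested = nrow(dmps),
            dmps_prioritized = nrow(prior),
            dmrs = length(dmrs),
            ora_sets = if (is.null(ora)) 0L else nrow(ora)))
    jsonlite::write_json(runManifest,
                         file.path(outDir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(list(qc = qc, dmps = dmps, prioritized = prior, dmrs = dmrs,
                   ora = ora, run_manifest = runManifest))
}
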