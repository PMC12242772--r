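.PIPELINE_DEFAULTS <- list(
    genomeFasta = NULL, captureSam = NULL, controlSam = NULL,
    longReadSam = NULL, cageBed = NULL, consensusFasta = NULL,
    outDir = "terraseq_out",
    motif = "TTAGGG", minTract = 200, maxGap = 24, minPurity = 0.8,
    endWindow = 100000, minIdentity = 0.8, minCopies = 2,
    enrThreshold = 1, pseudocount = 1, binSize = 30, minEvidence = 2,
    mode = "total", libraryLayout = "paired", strandedness = "none",
    cpmThreshold = 1, windowFrac = 0.05, cageWindow = 50,
    seed = 1, logLevel = "info")

#' Assemble and validate a pipeline configuration
#'
#' Merges user settings over the documented defaults; unknown keys are
#' rejected. The fully resolved configuration is written alongside the
#' outputs of every [runTerraPipeline()] run.
#'
#' @param ... named settings, or a single named list; see
#'   [runTerraPipeline()] for the meaning of the path entries and the
#'   module functions for the parameters.
#' @return A named list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(...) {
    args <- list(...)
    if (length(args) == 1L && is.list(args[[1L]]) && is.null(names(args)))
        args <- args[[1L]]
    unknown <- setdiff(names(args), names(.PIPELINE_DEFAULTS))
    if (length(unknown))
        stop("unknown configuration keys: ",
             paste(unknown, collapse = ", "), call. = FALSE)
    cfg <- utils::modifyList(.PIPELINE_DEFAULTS, args)
    structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of configuration keys.
#' @return A `"PipelineConfig"` list.
#' @export
readPipelineConfig <- function(path) {
    pipelineConfig(yaml::read_yaml(path))
}

.logmsg <- function(con, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    paste0(...))
    message(line)
    if (!is.null(con)) writeLines(line, con)
}

#' Run the TERRA annotation and quantification pipeline
#'
#' Executes tract scanning, promoter-element detection, region calling,
#' counting and (when several samples are provided) normalization over
#' the configured inputs, writing all outputs plus the resolved
#' configuration and a provenance log to `cfg$outDir`. Inputs are never
#' mutated; reruns with the same configuration produce identical
#' outputs.
#'
#' Inputs (all paths in the configuration): `genomeFasta` (required);
#' `captureSam`/`controlSam` for short-read coverage enrichment;
#' `longReadSam` for filtered long-read 5' ends; `cageBed` for CAGE
#' tags; `consensusFasta` for real 61/29/37 element consensuses
#' (defaults to the synthetic built-ins).
#'
#' @param cfg a [pipelineConfig()] (or plain named list of settings).
#' @return Invisibly, a list with the main in-memory results
#'   (`tracts`, `arrays`, `regions`, `counts`, `totals`).
#' @export
runTerraPipeline <- function(cfg) {
    if (!inherits(cfg, "PipelineConfig")) cfg <- pipelineConfig(cfg)
    if (is.null(cfg$genomeFasta) || !file.exists(cfg$genomeFasta))
        stop("genomeFasta is required and must exist", call. = FALSE)
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    logPath <- file.path(cfg$outDir, "run.log")
    con <- file(logPath, open = "wt")
    on.exit(close(con), add = TRUE)
    yaml::write_yaml(unclass(cfg), file.path(cfg$outDir, "config.yaml"))
    .logmsg(con, "terraseq pipeline start")
    for (p in c("genomeFasta", "captureSam", "controlSam", "longReadSam",
                "cageBed", "consensusFasta")) {
        if (!is.null(cfg[[p]])) {
            if (!all(file.exists(cfg[[p]])))
                stop("missing input file for ", p, ": ", cfg[[p]],
                     call. = FALSE)
            .logmsg(con, p, ": ", paste(cfg[[p]], collapse = ","),
                    " md5=", paste(tools::md5sum(cfg[[p]]), collapse = ","))
        }
    }
    genome <- readDNAStringSet(cfg$genomeFasta)
    names(genome) <- sub("\\s.*$", "", names(genome))
    seqLengths <- setNames(BiocGenerics::width(genome), names(genome))

    .logmsg(con, "scanning for telomeric repeat tracts")
    tracts <- scanGenome(genome, motif = cfg$motif,
                         minTract = cfg$minTract, maxGap = cfg$maxGap,
                         minPurity = cfg$minPurity,
                         endWindow = cfg$endWindow)
    exportTractsBed(tracts, file.path(cfg$outDir, "tracts.bed"))

    .logmsg(con, "scanning for promoter element arrays")
    cons <- if (is.null(cfg$consensusFasta)) elementConsensuses()
            else readElementConsensuses(cfg$consensusFasta)
    arrays <- findAllElementArrays(genome, cons, minCopies = cfg$minCopies,
                                   minIdentity = cfg$minIdentity)

    enrichment <- NULL
    capAln <- NULL
    if (!is.null(cfg$captureSam) && !is.null(cfg$controlSam)) {
        .logmsg(con, "computing capture/control enrichment")
        capAln <- readAlignments(cfg$captureSam)
        ctrlAln <- readAlignments(cfg$controlSam)
        enrichment <- lapply(names(seqLengths), function(sid) {
            cap <- coverageFromAlignments(capAln, sid, seqLengths[[sid]],
                                          binSize = cfg$binSize,
                                          normalization = "RPKM",
                                          librarySize = nrow(capAln))
            ctl <- coverageFromAlignments(ctrlAln, sid, seqLengths[[sid]],
                                          binSize = cfg$binSize,
                                          normalization = "RPKM",
                                          librarySize = nrow(ctrlAln))
            log2Enrichment(cap, ctl, pseudocount = cfg$pseudocount)
        })
        names(enrichment) <- names(seqLengths)
        for (sid in names(enrichment))
            exportBedGraph(enrichment[[sid]],
                           file.path(cfg$outDir,
                                     paste0("enrichment_", sid, ".bedGraph")))
    }

    fivep <- NULL
    if (!is.null(cfg$longReadSam)) {
        .logmsg(con, "extracting long-read 5' ends")
        lrAln <- filterLongReadAlignments(readAlignments(cfg$longReadSam))
        if (NROW(lrAln)) {
            pos <- ifelse(lrAln$strand == "+", lrAln$start, lrAln$end)
            fivep <- GRanges(lrAln$seq_id, IRanges(pos, width = 1L),
                             strand = lrAln$strand)
        }
    }

    cage <- NULL
    if (!is.null(cfg$cageBed)) {
        tags <- import(cfg$cageBed, format = "BED")
        cage <- clusterCageTags(GRanges(GenomeInfoDb::seqnames(tags),
                                        IRanges(BiocGenerics::start(tags),
                                                width = 1L),
                                        strand = BiocGenerics::strand(tags)),
                                window = cfg$cageWindow)
    }

    .logmsg(con, "calling TERRA transcription regions")
    regions <- callTerraRegions(tracts, seqLengths, enrichment = enrichment,
                                fivePrimeEnds = fivep, cage = cage,
                                arrays = arrays, endWindow = cfg$endWindow,
                                enrThreshold = cfg$enrThreshold,
                                minEvidence = cfg$minEvidence)
    exportRegions(regions, file.path(cfg$outDir, "regions.bed"),
                  file.path(cfg$outDir, "regions.gtf"))
    .logmsg(con, length(regions), " regions called; no TERRA detected: ",
            paste(metadata(regions)$no_terra, collapse = ",") )

    counts <- NULL; totals <- NULL
    if (!is.null(capAln) && length(regions)) {
        .logmsg(con, "counting fragments (mode=", cfg$mode, ")")
        counts <- countReads(list(capture = capAln), regions,
                             mode = cfg$mode,
                             libraryLayout = cfg$libraryLayout,
                             strandedness = cfg$strandedness)
        writeCountsTsv(counts, file.path(cfg$outDir, "counts.tsv"))
        if (cfg$mode == "total") {
            totals <- totalTerra(counts)
            utils::write.table(
                data.frame(sample = names(totals), total_terra = totals),
                file.path(cfg$outDir, "total_terra.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
        }
    }
    .logmsg(con, "terraseq pipeline done")
    invisible(list(tracts = tracts, arrays = arrays, regions = regions,
                   counts = counts, totals = totals))
}
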