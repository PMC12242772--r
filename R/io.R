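#' @importFrom rtracklayer import export
#' @importFrom Rsamtools asBam ScanBamParam scanBamFlag
#' @importFrom GenomicAlignments readGAlignments
NULL

#' Write alignment records as SAM
#'
#' Serializes an alignment data.frame (the simulator's native output) to
#' a plain-text SAM file with a sorted-order header. Mates of paired
#' records are linked by `read_id` for RNEXT/PNEXT/TLEN. SEQ/QUAL are
#' omitted (`*`) unless a `seq` column is present; CIGAR defaults to a
#' full-length match over the reference span.
#'
#' @param aln alignment data.frame (`read_id`, `seq_id`, `start`, `end`,
#'   `mapq`, `flag`, optional `cigar`, `seq`).
#' @param seqLengths named vector of reference sequence lengths for the
#'   `@SQ` header lines.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSam <- function(aln, seqLengths, path) {
    aln <- .checkAlignments(aln)
    aln <- aln[order(aln$seq_id, aln$start), , drop = FALSE]
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", names(seqLengths),
                     as.integer(seqLengths)))
    cigar <- if ("cigar" %in% colnames(aln)) aln$cigar
             else paste0(aln$end - aln$start + 1L, "M")
    seqF <- if ("seq" %in% colnames(aln)) aln$seq else "*"
    bits <- flagBits(aln$flag)
    rnext <- ifelse(bits[, "paired"], "=", "*")
    pnext <- rep(0L, NROW(aln))
    tlen <- rep(0L, NROW(aln))
    if (any(bits[, "paired"])) {
        key <- paste(aln$read_id)
        sp <- split(seq_len(NROW(aln)), key)
        for (idx in sp) {
            if (length(idx) == 2L) {
                pnext[idx] <- aln$start[rev(idx)]
                span <- max(aln$end[idx]) - min(aln$start[idx]) + 1L
                tlen[idx] <- ifelse(aln$start[idx] <= aln$start[rev(idx)],
                                    span, -span)
            }
        }
    }
    rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
                   aln$read_id, as.integer(aln$flag), aln$seq_id,
                   as.integer(aln$start), as.integer(aln$mapq), cigar,
                   rnext, pnext, tlen, seqF)
    writeLines(c(hdr, rec), path)
    invisible(path)
}

#' Read alignments from SAM or BAM
#'
#' Reads a SAM (converted on the fly) or BAM file into the package's
#' alignment data.frame representation: 1-based closed reference
#' coordinates, one row per record, columns `read_id`, `seq_id`,
#' `start`, `end`, `strand`, `mapq`, `flag`. Unmapped records are
#' dropped; missing MAPQ is read as 0.
#'
#' @param path a `.sam` or `.bam` file.
#' @return Alignment data.frame, coordinate-sorted.
#' @export
readAlignments <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    bam <- path
    if (grepl("\\.sam$", path, ignore.case = TRUE))
        bam <- asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
    ga <- readGAlignments(bam, param = ScanBamParam(
        what = c("qname", "flag", "mapq"),
        flag = scanBamFlag(isUnmappedQuery = FALSE)))
    mq <- S4Vectors::mcols(ga)$mapq
    mq[is.na(mq)] <- 0L
    df <- data.frame(
        read_id = S4Vectors::mcols(ga)$qname,
        seq_id = as.character(GenomeInfoDb::seqnames(ga)),
        start = BiocGenerics::start(ga),
        end = BiocGenerics::end(ga),
        strand = as.character(BiocGenerics::strand(ga)),
        mapq = mq,
        flag = S4Vectors::mcols(ga)$flag,
        stringsAsFactors = FALSE)
    df[order(df$seq_id, df$start), , drop = FALSE]
}

#' Export repeat tracts as BED6
#'
#' BED output is 0-based half-open; the name field carries the tract
#' category and the score `round(1000 * purity)`.
#'
#' @param tracts classified tract `GRanges`.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
exportTractsBed <- function(tracts, path) {
    gr <- granges(tracts)
    gr$name <- ifelse(is.na(tracts$category), "unclassified",
                      tracts$category)
    gr$score <- as.integer(round(1000 * tracts$purity))
    export(gr, path, format = "BED")
    invisible(path)
}

#' Export/import a CoverageTrack as bedGraph
#'
#' @param track a [CoverageTrack-class].
#' @param path bedGraph file.
#' @return `path` (export) or a `CoverageTrack` (import).
#' @export
exportBedGraph <- function(track, path) {
    stopifnot(is(track, "CoverageTrack"))
    nb <- length(track@values)
    b <- track@binSize
    gr <- GRanges(track@seqId,
                  IRanges((seq_len(nb) - 1L) * b + 1L,
                          pmin(seq_len(nb) * b, track@seqLen)),
                  score = track@values)
    export(gr, path, format = "bedGraph")
    invisible(path)
}

#' @rdname exportBedGraph
#' @param seqLen,binSize,normalization grid parameters of the track being
#'   read back (bedGraph itself does not carry them).
#' @export
importBedGraph <- function(path, seqLen, binSize = 30L,
                           normalization = "raw") {
    gr <- import(path, format = "bedGraph")
    sid <- as.character(GenomeInfoDb::seqnames(gr))[1L]
    nb <- as.integer(ceiling(seqLen / binSize))
    v <- numeric(nb)
    bin <- (BiocGenerics::start(gr) - 1L) %/% binSize + 1L
    v[bin] <- gr$score
    coverageTrack(sid, seqLen, v, binSize = binSize,
                  normalization = normalization)
}

#' Export TERRA regions as BED6 and GTF
#'
#' The BED file (0-based half-open) holds one line per region named by
#' `region_id`. The GTF (1-based inclusive) holds one `transcript`
#' feature per region plus two child features (`subtelomeric`,
#' `telomeric`), with attributes carrying the type, TSS, rank, tract
#' category and promoter signature so that [importRegionsGtf()]
#' round-trips exactly.
#'
#' @param regions a [TerraRegions-class].
#' @param bedPath,gtfPath output paths (`NULL` to skip one of them).
#' @return Invisibly, the written paths.
#' @export
exportRegions <- function(regions, bedPath = NULL, gtfPath = NULL) {
    stopifnot(is(regions, "TerraRegions"))
    if (anyDuplicated(regionId(regions)))
        stop("duplicated region_id values", call. = FALSE)
    if (!is.null(bedPath)) {
        gr <- granges(regions)
        gr$name <- regionId(regions)
        gr$score <- 0L
        export(gr, bedPath, format = "BED")
    }
    if (!is.null(gtfPath)) {
        mc <- mcols(regions)
        sq <- as.character(GenomeInfoDb::seqnames(regions))
        strv <- as.character(BiocGenerics::strand(regions))
        attrs <- function(i) sprintf(
            paste0('region_id "%s"; terra_type "%s"; tss "%d"; ',
                   'tss_rank "%s"; tract_category "%s"; signature "%s";'),
            mc$region_id[i], mc$type[i], mc$tss[i], mc$tss_rank[i],
            mc$tract_category[i],
            paste0(as.integer(c(mc$has61[i], mc$has29[i], mc$has37[i])),
                   collapse = ""))
        lines <- unlist(lapply(seq_along(regions), function(i) {
            a <- attrs(i)
            c(sprintf("%s\tterraseq\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                      sq[i], BiocGenerics::start(regions)[i],
                      BiocGenerics::end(regions)[i], strv[i], a),
              sprintf("%s\tterraseq\tsubtelomeric\t%d\t%d\t.\t%s\t.\t%s",
                      sq[i], mc$subtel_start[i], mc$subtel_end[i],
                      strv[i], a),
              sprintf("%s\tterraseq\ttelomeric\t%d\t%d\t.\t%s\t.\t%s",
                      sq[i], mc$telo_start[i], mc$telo_end[i], strv[i], a))
        }))
        writeLines(c("##gff-version 2", lines), gtfPath)
    }
    invisible(c(bed = bedPath, gtf = gtfPath))
}

#' Import TERRA regions from the package's GTF
#'
#' @param path GTF written by [exportRegions()].
#' @return A [TerraRegions-class] object.
#' @export
importRegionsGtf <- function(path) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#")]
    emptyDf <- data.frame(seq_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          region_id = character(), type = character(),
                          tss = integer(), tss_rank = character(),
                          subtel_start = integer(), subtel_end = integer(),
                          telo_start = integer(), telo_end = integer(),
                          tract_category = character(), has61 = logical(),
                          has29 = logical(), has37 = logical())
    if (!length(ln)) return(terraRegions(emptyDf))
    f <- strsplit(ln, "\t", fixed = TRUE)
    getAttr <- function(a, key) sub(
        sprintf('.*%s "([^"]*)".*', key), "\\1", a)
    rows <- lapply(f, function(x) {
        a <- x[9L]
        data.frame(seq_id = x[1L], feature = x[3L],
                   start = as.integer(x[4L]), end = as.integer(x[5L]),
                   strand = x[7L],
                   region_id = getAttr(a, "region_id"),
                   type = getAttr(a, "terra_type"),
                   tss = as.integer(getAttr(a, "tss")),
                   tss_rank = getAttr(a, "tss_rank"),
                   tract_category = getAttr(a, "tract_category"),
                   signature = getAttr(a, "signature"),
                   stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    tr <- df[df$feature == "transcript", , drop = FALSE]
    sub <- df[df$feature == "subtelomeric", , drop = FALSE]
    tel <- df[df$feature == "telomeric", , drop = FALSE]
    m1 <- match(tr$region_id, sub$region_id)
    m2 <- match(tr$region_id, tel$region_id)
    out <- data.frame(
        seq_id = tr$seq_id, start = tr$start, end = tr$end,
        strand = tr$strand, region_id = tr$region_id, type = tr$type,
        tss = tr$tss, tss_rank = tr$tss_rank,
        subtel_start = sub$start[m1], subtel_end = sub$end[m1],
        telo_start = tel$start[m2], telo_end = tel$end[m2],
        tract_category = tr$tract_category,
        has61 = substr(tr$signature, 1L, 1L) == "1",
        has29 = substr(tr$signature, 2L, 2L) == "1",
        has37 = substr(tr$signature, 3L, 3L) == "1",
        stringsAsFactors = FALSE)
    terraRegions(out)
}

#' Write/read a count SummarizedExperiment as TSV
#'
#' The TSV holds the feature metadata columns followed by one column per
#' sample; [readCountsTsv()] restores the `SummarizedExperiment`.
#'
#' @param counts `SummarizedExperiment` from [countReads()].
#' @param path TSV file.
#' @return `path` (write) / `SummarizedExperiment` (read).
#' @export
writeCountsTsv <- function(counts, path) {
    rd <- as.data.frame(rowData(counts))
    m <- assay(counts, "counts")
    utils::write.table(cbind(rd, m), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCountsTsv
#' @export
readCountsTsv <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    meta <- c("feature_id", "region_id", "seq_id", "start", "end",
              "strand", "region_type", "subregion", "tss_rank")
    sampleCols <- setdiff(colnames(df), meta)
    m <- as.matrix(df[, sampleCols, drop = FALSE])
    rownames(m) <- df$feature_id
    SummarizedExperiment(
        assays = list(counts = m),
        rowData = DataFrame(df[, meta, drop = FALSE]),
        colData = DataFrame(sample_id = sampleCols,
                            row.names = sampleCols))
}

#' Write/read a simulation truth ledger as JSON
#'
#' @param truth the truth list from [simulateGenome()] (optionally
#'   augmented with read-level tables).
#' @param path JSON file.
#' @return `path` (write) / truth list (read).
#' @export
writeTruthJson <- function(truth, path) {
    if (!is.null(truth$seqLengths))
        truth$seqLengths <- as.list(truth$seqLengths)  # keep names in JSON
    jsonlite::write_json(truth, path, dataframe = "columns",
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeTruthJson
#' @export
readTruthJson <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    x$seqLengths <- unlist(x$seqLengths)
    x
}
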