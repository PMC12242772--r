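#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges granges
#' @importFrom IRanges IRanges
NULL

#' Binned coverage track over one sequence
#'
#' A `CoverageTrack` holds per-bin coverage (or derived log2-ratio) values
#' for a single reference sequence, on a fixed bin grid anchored at
#' coordinate 1. Bin \eqn{i} covers the 1-based interval
#' \eqn{[(i-1)b + 1, \min(ib, L)]} for bin size \eqn{b} and sequence length
#' \eqn{L}, so the number of bins is `ceiling(L / b)`.
#'
#' @slot seqId character(1), name of the reference sequence.
#' @slot seqLen integer(1), sequence length in bp.
#' @slot binSize integer(1), bin width in bp (30 by default elsewhere).
#' @slot values numeric vector of per-bin values, all finite.
#' @slot normalization character(1), one of `"raw"`, `"RPKM"`, `"CPM"`,
#'   `"log2ratio"`.
#'
#' @seealso [coverageTrack()], [coverageFromAlignments()], [log2Enrichment()]
#' @export
setClass("CoverageTrack",
    representation(
        seqId = "character",
        seqLen = "integer",
        binSize = "integer",
        values = "numeric",
        normalization = "character"
    )
)

setValidity("CoverageTrack", function(object) {
    msg <- character()
    if (length(object@seqId) != 1L || is.na(object@seqId) || !nzchar(object@seqId))
        msg <- c(msg, "'seqId' must be a single non-empty string")
    if (length(object@binSize) != 1L || is.na(object@binSize) || object@binSize < 1L)
        msg <- c(msg, "'binSize' must be a single positive integer")
    if (length(object@seqLen) != 1L || is.na(object@seqLen) || object@seqLen < 1L)
        msg <- c(msg, "'seqLen' must be a single positive integer")
    if (!object@normalization %in% c("raw", "RPKM", "CPM", "log2ratio"))
        msg <- c(msg, "'normalization' must be one of raw/RPKM/CPM/log2ratio")
    if (any(!is.finite(object@values)))
        msg <- c(msg, "all 'values' must be finite")
    nb <- as.integer(ceiling(object@seqLen / object@binSize))
    if (length(object@values) != nb)
        msg <- c(msg, sprintf("expected %d bins for seqLen %d at binSize %d, got %d",
                              nb, object@seqLen, object@binSize, length(object@values)))
    if (length(msg)) msg else TRUE
})

#' Construct a CoverageTrack
#'
#' @param seqId sequence name.
#' @param seqLen sequence length (bp).
#' @param values per-bin values; length must be `ceiling(seqLen / binSize)`.
#' @param binSize bin width in bp.
#' @param normalization value scale tag.
#' @return A [CoverageTrack-class] object.
#' @examples
#' coverageTrack("chr1", 100, values = rep(0, 4), binSize = 30)
#' @export
coverageTrack <- function(seqId, seqLen, values, binSize = 30L,
                          normalization = c("raw", "RPKM", "CPM", "log2ratio")) {
    normalization <- match.arg(normalization)
    new("CoverageTrack", seqId = as.character(seqId),
        seqLen = as.integer(seqLen), binSize = as.integer(binSize),
        values = as.numeric(values), normalization = normalization)
}

#' @describeIn CoverageTrack-class number of bins
#' @param x,object a `CoverageTrack`
#' @export
setMethod("length", "CoverageTrack", function(x) length(x@values))

#' @describeIn CoverageTrack-class per-bin values
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname CoverageTrack-class
#' @export
setMethod("trackValues", "CoverageTrack", function(x) x@values)

#' @describeIn CoverageTrack-class bin width (bp)
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname CoverageTrack-class
#' @export
setMethod("binSize", "CoverageTrack", function(x) x@binSize)

setMethod("show", "CoverageTrack", function(object) {
    cat(sprintf("CoverageTrack on %s (%d bp): %d bins of %d bp, %s\n",
                object@seqId, object@seqLen, length(object@values),
                object@binSize, object@normalization))
    v <- object@values
    cat(sprintf("  values: min %.3g, median %.3g, max %.3g\n",
                min(v), stats::median(v), max(v)))
})

.REGION_MCOLS <- c("region_id", "type", "tss", "tss_rank",
                   "subtel_start", "subtel_end", "telo_start", "telo_end",
                   "tract_category", "has61", "has29", "has37")

#' Set of TERRA transcription regions
#'
#' `TerraRegions` extends `GRanges`. Each range is one TERRA transcription
#' unit running from its transcription start site (TSS) to the distal edge
#' of its telomeric repeat tract, on the strand of transcription (the
#' strand on which the transcript reads into UUAGGG repeats). Required
#' metadata columns:
#'
#' \describe{
#'   \item{region_id}{unique region name, e.g. `"chr22q"` or `"ITS_chr2_1"`.}
#'   \item{type}{`"I"`, `"II"` or `"III"`: chromosome-end regions with
#'     61/29/37 bp promoter elements (I), chromosome-end regions lacking
#'     them (II), interstitial-telomeric-sequence regions (III).}
#'   \item{tss}{TSS coordinate (1-based).}
#'   \item{tss_rank}{`"proximal"` or `"distal"` (relative to the telomere);
#'     arms can carry a second, telomere-distal TSS.}
#'   \item{subtel_start, subtel_end}{the subtelomeric sub-interval
#'     (1-based closed).}
#'   \item{telo_start, telo_end}{the telomeric repeat tract sub-interval.}
#'   \item{tract_category}{category of the underlying tract
#'     (`terminal_p`, `terminal_q`, `interstitial`).}
#'   \item{has61, has29, has37}{promoter-element signature flags, scored
#'     over the 3 kb window upstream of the TSS.}
#' }
#'
#' Validity enforces that the subtelomeric and telomeric sub-intervals are
#' disjoint and tile the region exactly, that Type III regions (and only
#' those) sit on interstitial tracts, that Type I regions carry at least
#' one promoter element and Type II regions none.
#'
#' @seealso [terraRegions()], [callTerraRegions()], [classifyRegion()]
#' @export
setClass("TerraRegions", contains = "GRanges")

setValidity("TerraRegions", function(object) {
    mc <- mcols(object)
    missing <- setdiff(.REGION_MCOLS, colnames(mc))
    if (length(missing))
        return(sprintf("missing metadata columns: %s",
                       paste(missing, collapse = ", ")))
    if (length(object) == 0L) return(TRUE)
    msg <- character()
    if (anyDuplicated(mc$region_id))
        msg <- c(msg, "region_id values must be unique")
    if (!all(mc$type %in% c("I", "II", "III")))
        msg <- c(msg, "type must be I, II or III")
    if (!all(mc$tss_rank %in% c("proximal", "distal")))
        msg <- c(msg, "tss_rank must be proximal or distal")
    st <- BiocGenerics::start(object); en <- BiocGenerics::end(object)
    subOK <- mc$subtel_start <= mc$subtel_end
    telOK <- mc$telo_start <= mc$telo_end
    disjoint <- mc$subtel_end < mc$telo_start | mc$telo_end < mc$subtel_start
    tile <- (pmin(mc$subtel_start, mc$telo_start) == st) &
            (pmax(mc$subtel_end, mc$telo_end) == en) &
            (mc$subtel_end - mc$subtel_start + 1) +
            (mc$telo_end - mc$telo_start + 1) == en - st + 1
    if (!all(subOK & telOK & disjoint & tile))
        msg <- c(msg, "subtelomeric and telomeric intervals must be disjoint and tile the region")
    if (!all((mc$type == "III") == (mc$tract_category == "interstitial")))
        msg <- c(msg, "type III regions must sit on interstitial tracts (and only those)")
    anyEl <- mc$has61 | mc$has29 | mc$has37
    if (!all(anyEl[mc$type == "I"]))
        msg <- c(msg, "type I regions must carry at least one promoter element")
    if (any(anyEl[mc$type == "II"]))
        msg <- c(msg, "type II regions must have an empty promoter signature")
    if (!all(mc$tss >= st & mc$tss <= en))
        msg <- c(msg, "tss must lie within the region")
    if (length(msg)) msg else TRUE
})

#' Construct a TerraRegions object
#'
#' @param gr a `GRanges` carrying the metadata columns documented in
#'   [TerraRegions-class], or a `data.frame` with columns `seq_id`,
#'   `start`, `end`, `strand` plus those metadata columns.
#' @return A validated [TerraRegions-class] object.
#' @export
terraRegions <- function(gr) {
    if (is.data.frame(gr)) {
        df <- gr
        gr <- GRanges(df$seq_id, IRanges(df$start, df$end), strand = df$strand)
        mcols(gr) <- DataFrame(df[, intersect(.REGION_MCOLS, colnames(df)),
                                  drop = FALSE])
    }
    new("TerraRegions", gr)
}

#' @describeIn TerraRegions-class region identifiers
#' @param x a `TerraRegions` object
#' @export
setGeneric("regionId", function(x) standardGeneric("regionId"))

#' @rdname TerraRegions-class
#' @export
setMethod("regionId", "TerraRegions", function(x) mcols(x)$region_id)

#' @describeIn TerraRegions-class region types (I/II/III)
#' @export
setGeneric("regionType", function(x) standardGeneric("regionType"))

#' @rdname TerraRegions-class
#' @export
setMethod("regionType", "TerraRegions", function(x) mcols(x)$type)

#' @describeIn TerraRegions-class TSS coordinates
#' @export
setGeneric("regionTss", function(x) standardGeneric("regionTss"))

#' @rdname TerraRegions-class
#' @export
setMethod("regionTss", "TerraRegions", function(x) mcols(x)$tss)

#' @describeIn TerraRegions-class subtelomeric sub-intervals as GRanges
#' @export
setGeneric("subtelomericRanges", function(x) standardGeneric("subtelomericRanges"))

#' @rdname TerraRegions-class
#' @export
setMethod("subtelomericRanges", "TerraRegions", function(x) {
    mc <- mcols(x)
    gr <- GRanges(GenomeInfoDb::seqnames(x),
                  IRanges(mc$subtel_start, mc$subtel_end),
                  strand = BiocGenerics::strand(x))
    names(gr) <- mc$region_id
    gr
})

#' @describeIn TerraRegions-class telomeric sub-intervals as GRanges
#' @export
setGeneric("telomericRanges", function(x) standardGeneric("telomericRanges"))

#' @rdname TerraRegions-class
#' @export
setMethod("telomericRanges", "TerraRegions", function(x) {
    mc <- mcols(x)
    gr <- GRanges(GenomeInfoDb::seqnames(x),
                  IRanges(mc$telo_start, mc$telo_end),
                  strand = BiocGenerics::strand(x))
    names(gr) <- mc$region_id
    gr
})

#' @describeIn TerraRegions-class promoter-element signature matrix
#' @export
setGeneric("regionSignature", function(x) standardGeneric("regionSignature"))

#' @rdname TerraRegions-class
#' @export
setMethod("regionSignature", "TerraRegions", function(x) {
    mc <- mcols(x)
    m <- cbind(has61 = mc$has61, has29 = mc$has29, has37 = mc$has37)
    rownames(m) <- mc$region_id
    m
})

setMethod("show", "TerraRegions", function(object) {
    tab <- table(factor(regionType(object), levels = c("I", "II", "III")))
    cat(sprintf("TerraRegions with %d regions (Type I: %d, II: %d, III: %d)\n",
                length(object), tab[["I"]], tab[["II"]], tab[["III"]]))
    methods::callNextMethod()
})
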