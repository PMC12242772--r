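#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

# features for a counting mode: data.frame(feature_id, region_id, seq_id,
# start, end, strand, region_type, subregion, tss_rank)
.modeFeatures <- function(regions, mode) {
    mc <- mcols(regions)
    sq <- as.character(GenomeInfoDb::seqnames(regions))
    strv <- as.character(BiocGenerics::strand(regions))
    base <- data.frame(region_id = mc$region_id, seq_id = sq, strand = strv,
                       region_type = mc$type, tss_rank = mc$tss_rank,
                       stringsAsFactors = FALSE)
    if (mode == "capture") {
        f <- cbind(base, start = BiocGenerics::start(regions),
                   end = BiocGenerics::end(regions), subregion = "region")
        f$feature_id <- f$region_id
        return(f)
    }
    sub <- cbind(base, start = mc$subtel_start, end = mc$subtel_end,
                 subregion = "subtelomeric")
    sub$feature_id <- paste0(sub$region_id, "_subtel")
    if (mode == "arm_specific") return(sub)
    tel <- cbind(base, start = mc$telo_start, end = mc$telo_end,
                 subregion = "telomeric")
    tel$feature_id <- paste0(tel$region_id, "_telo")
    f <- rbind(sub, tel)
    f[order(f$seq_id, f$start), , drop = FALSE]
}

# collapse alignment records into fragments for counting.
# paired layout: mates (same read_id, paired flag) form one fragment
# spanning the union of mate reference spans; fragment strand is the
# strand of the first-in-pair mate. single layout: record = fragment.
.toFragments <- function(aln, libraryLayout) {
    if (NROW(aln) == 0L)
        return(data.frame(read_id = character(), seq_id = character(),
                          start = integer(), end = integer(),
                          strand = character()))
    bits <- flagBits(aln$flag)
    if (libraryLayout == "single" || !any(bits[, "paired"])) {
        return(data.frame(read_id = aln$read_id, seq_id = aln$seq_id,
                          start = as.integer(aln$start),
                          end = as.integer(aln$end),
                          strand = aln$strand, stringsAsFactors = FALSE))
    }
    key <- paste(aln$read_id, aln$seq_id)
    first <- bits[, "first_in_pair"] | !bits[, "paired"]
    sp <- split(seq_len(NROW(aln)), key)
    rows <- lapply(sp, function(idx) {
        fs <- idx[first[idx]]
        sidx <- if (length(fs)) fs[1L] else idx[1L]
        data.frame(read_id = aln$read_id[idx[1L]],
                   seq_id = aln$seq_id[idx[1L]],
                   start = min(as.integer(aln$start[idx])),
                   end = max(as.integer(aln$end[idx])),
                   strand = aln$strand[sidx], stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# duplicate removal on records: flag-based when duplicate flags are set,
# else positional (identical seq_id/start/end/strand collapse)
.dedupRecords <- function(aln, dedup) {
    if (NROW(aln) == 0L || dedup == "none") return(aln)
    bits <- flagBits(aln$flag)
    if (dedup == "auto")
        dedup <- if (any(bits[, "duplicate"])) "flag" else "position"
    if (dedup == "flag") return(aln[!bits[, "duplicate"], , drop = FALSE])
    key <- paste(aln$seq_id, aln$start, aln$end, aln$strand,
                 bits[, "first_in_pair"])
    aln[!duplicated(key), , drop = FALSE]
}

.filterMode <- function(aln, mode, libraryLayout, dedup) {
    bits <- flagBits(aln$flag)
    if (mode == "arm_specific") {
        keep <- if (libraryLayout == "paired") aln$mapq >= 30L
                else aln$mapq == 255L
        aln[keep, , drop = FALSE]
    } else if (mode == "total") {
        aln <- aln[bits[, "primary"] & aln$mapq >= 1L, , drop = FALSE]
        .dedupRecords(aln, dedup)
    } else {                                   # capture
        aln[aln$mapq >= 30L, , drop = FALSE]
    }
}

#' Count RNA-seq fragments over TERRA regions
#'
#' Region-based counting under mode-specific filters:
#' \describe{
#'   \item{`arm_specific`}{records with MAPQ >= 30 (paired layout) or
#'     MAPQ = 255 (single layout, the aligner's unique-mapping
#'     convention); only overlaps with the *subtelomeric* sub-interval of
#'     each region are counted, the basis of chromosome-arm-specific
#'     TERRA.}
#'   \item{`total`}{primary alignments with MAPQ >= 1, duplicates
#'     removed; both the subtelomeric and telomeric sub-intervals are
#'     counted as separate features.}
#'   \item{`capture`}{records with MAPQ >= 30, counted over whole
#'     regions.}
#' }
#'
#' A read pair counts as one fragment (the union of the mate spans); a
#' fragment overlapping a feature by at least 1 bp counts, and a fragment
#' overlapping several features counts once in each (nonunique-all
#' semantics). When `strandedness` is not `"none"`, the fragment
#' orientation must match (`forward`) or oppose (`reverse`) the region
#' strand.
#'
#' @param alignments one alignment data.frame, or a named list of them
#'   (one per sample).
#' @param regions a [TerraRegions-class] object.
#' @param mode `"arm_specific"`, `"total"` or `"capture"`.
#' @param libraryLayout `"paired"` or `"single"`.
#' @param strandedness `"none"`, `"forward"` or `"reverse"`.
#' @param dedup duplicate handling in total mode: `"auto"` (flag-based if
#'   duplicate flags are present, else positional), `"flag"`,
#'   `"position"`, `"none"`.
#' @return A `SummarizedExperiment` of integer counts with feature
#'   metadata (`region_id`, `region_type`, `subregion`, `tss_rank`) in
#'   `rowData`.
#' @export
countReads <- function(alignments, regions,
                       mode = c("total", "arm_specific", "capture"),
                       libraryLayout = c("paired", "single"),
                       strandedness = c("none", "forward", "reverse"),
                       dedup = c("auto", "flag", "position", "none")) {
    mode <- match.arg(mode)
    libraryLayout <- match.arg(libraryLayout)
    strandedness <- match.arg(strandedness)
    dedup <- match.arg(dedup)
    stopifnot(is(regions, "TerraRegions"))
    if (is.data.frame(alignments)) alignments <- list(sample1 = alignments)
    if (is.null(names(alignments)))
        names(alignments) <- paste0("sample", seq_along(alignments))
    feats <- .modeFeatures(regions, mode)
    counts <- matrix(0L, nrow = nrow(feats), ncol = length(alignments),
                     dimnames = list(feats$feature_id, names(alignments)))
    regSeqs <- unique(feats$seq_id)
    for (s in seq_along(alignments)) {
        aln <- .checkAlignments(alignments[[s]])
        if (NROW(aln) &&
            any(vapply(split(as.integer(aln$start), aln$seq_id),
                       is.unsorted, logical(1))))
            stop("alignments must be coordinate-sorted", call. = FALSE)
        unknown <- setdiff(unique(aln$seq_id), regSeqs)
        if (length(unknown))
            warning("skipping alignments on sequences without regions: ",
                    paste(unknown, collapse = ", "), call. = FALSE)
        aln <- .filterMode(aln, mode, libraryLayout, dedup)
        frags <- .toFragments(aln, libraryLayout)
        if (!NROW(frags)) next
        fgr <- GRanges(frags$seq_id,
                       IRanges(frags$start, frags$end), strand = frags$strand)
        tgr <- GRanges(feats$seq_id, IRanges(feats$start, feats$end),
                       strand = feats$strand)
        ov <- suppressWarnings(
            GenomicRanges::findOverlaps(fgr, tgr, ignore.strand = TRUE))
        qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
        if (strandedness != "none") {
            same <- frags$strand[qh] == feats$strand[sh]
            keep <- if (strandedness == "forward") same else !same
            qh <- qh[keep]; sh <- sh[keep]
        }
        if (length(sh)) {
            tab <- table(sh)
            counts[as.integer(names(tab)), s] <- as.integer(tab)
        }
    }
    SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(feats[, c("feature_id", "region_id", "seq_id",
                                      "start", "end", "strand",
                                      "region_type", "subregion",
                                      "tss_rank")]),
        colData = DataFrame(sample_id = names(alignments),
                            row.names = names(alignments)))
}

#' Total TERRA per sample
#'
#' Sums, per sample, the counts of all features belonging to Type I or
#' Type II regions with a telomere-proximal TSS — both the subtelomeric
#' and telomeric sub-features — excluding Type III (interstitial)
#' regions. This is the chromosome-end TERRA total used for cross-sample
#' comparisons.
#'
#' @param counts a `SummarizedExperiment` from [countReads()] (total
#'   mode), or any count matrix-like with `rowData` columns
#'   `region_type` and `tss_rank`.
#' @return Named numeric vector of per-sample totals.
#' @export
totalTerra <- function(counts) {
    rd <- rowData(counts)
    keep <- rd$region_type %in% c("I", "II") & rd$tss_rank == "proximal"
    m <- assay(counts, "counts")[keep, , drop = FALSE]
    colSums(m)
}

#' Counts per million mapped reads
#'
#' @param counts count matrix or `SummarizedExperiment`.
#' @param librarySizes per-sample totals of *mapped fragments in the
#'   whole library* (not the TERRA subtotal), recycled against columns.
#' @return Numeric matrix of CPM values.
#' @export
cpmMatrix <- function(counts, librarySizes) {
    m <- if (is(counts, "SummarizedExperiment")) assay(counts, "counts")
         else as.matrix(counts)
    stopifnot(length(librarySizes) == ncol(m), all(librarySizes > 0))
    sweep(m, 2L, librarySizes, function(x, n) x * 1e6 / n)
}

# per-region totals from a counts input: SummarizedExperiment (features
# collapsed by region_id, first sample), or a named numeric vector
.regionTotals <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        rd <- rowData(x)
        v <- assay(x, "counts")[, 1L]
        tapply(v, rd$region_id, sum)
    } else {
        stopifnot(!is.null(names(x)))
        x
    }
}

#' Poly(A)+/- partitioning of TERRA reads
#'
#' For matched poly(A)+ and poly(A)- libraries counted over the same
#' TERRA regions (Types I, II and III together forming the total TERRA
#' read pool of each fraction), computes each region's proportion of its
#' fraction's total TERRA reads, and the log2 ratio of the poly(A)+
#' proportion over the poly(A)- proportion. Regions with zero reads in
#' either fraction get an undefined (flagged) ratio.
#'
#' @param countsPlus,countsMinus per-region counts over identical region
#'   sets: `SummarizedExperiment`s from [countReads()] or named numeric
#'   vectors keyed by region id.
#' @return A data.frame with columns `region_id`, `frac_plus`,
#'   `frac_minus`, `log2_ratio`, `defined`.
#' @examples
#' p <- c(A = 20, B = 80); m <- c(A = 5, B = 95)
#' polyaEnrichment(p, m)$log2_ratio[1]  # exactly 2
#' @export
polyaEnrichment <- function(countsPlus, countsMinus) {
    p <- .regionTotals(countsPlus)
    m <- .regionTotals(countsMinus)
    ids <- names(p)
    if (!setequal(ids, names(m)))
        stop("the two fractions cover different region sets", call. = FALSE)
    m <- m[ids]
    if (sum(p) == 0 || sum(m) == 0)
        stop("a fraction has zero total TERRA reads", call. = FALSE)
    fp <- as.numeric(p) / sum(p)
    fm <- as.numeric(m) / sum(m)
    defined <- fp > 0 & fm > 0
    lr <- ifelse(defined, log2(fp / fm), NA_real_)
    data.frame(region_id = ids, frac_plus = fp, frac_minus = fm,
               log2_ratio = lr, defined = defined,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Pearson correlation of paired per-region values
#'
#' Standard Pearson correlation with the two-sided t-approximation
#' p-value, for comparing e.g. poly(A) log2 ratios between samples.
#'
#' @param x,y paired numeric vectors; pairs with `NA` in either are
#'   dropped.
#' @return A list with `pearson_r`, `p_value` and `n`.
#' @export
correlateRatios <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                          alternative = "two.sided")
    list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
         n = sum(ok))
}
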