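#' Detect telomeric repeat tracts in a DNA sequence
#'
#' Scans one sequence for runs of a telomeric repeat unit (canonically
#' `TTAGGG`) on both orientations. Exact motif occurrences on one
#' orientation separated by at most `maxGap` bp are chained into a
#' candidate tract; candidates whose span is at least `minTract` bp and
#' whose purity (fraction of the span covered by exact motif copies) is at
#' least `minPurity` are reported, trimmed to the outermost exact motif
#' match. Strand `+` means the G-rich motif reads on the sequence as
#' written; `-` means its reverse complement (`CCCTAA`) does.
#'
#' `N` bases never match the motif and therefore count against purity.
#' Degenerate repeat variants (`TGAGGG`, `TCAGGG`, ...) are not matched
#' unless supplied through `motifSet`.
#'
#' @param seq a `DNAString` or single character string (A/C/G/T/N only).
#' @param motif the 6-bp repeat unit (default `"TTAGGG"`).
#' @param minTract minimum tract span in bp (default 200, the conventional
#'   cutoff for calling interstitial telomeric sequences; tracts must be
#'   strictly longer than `minTract - 1`, i.e. span `>= minTract`).
#' @param maxGap maximum gap (bp) between chained motif occurrences.
#' @param minPurity minimum purity in (0, 1].
#' @param seqId sequence name used in the output.
#' @param motifSet optional character vector of additional 6-bp repeat
#'   variants to match alongside `motif`.
#' @return A `GRanges` (1-based closed coordinates) with metadata columns
#'   `unit_count` (number of exact, non-overlapping motif copies),
#'   `purity` = `6 * unit_count / width`, and `category` (`NA` until
#'   [classifyTracts()] is applied), sorted by start.
#' @examples
#' tr <- findRepeatTracts(strrep("TTAGGG", 40), minTract = 200)
#' width(tr)        # 240
#' tr$purity        # 1
#' @seealso [classifyTracts()], [scanGenome()], [measureReadTract()]
#' @export
findRepeatTracts <- function(seq, motif = "TTAGGG", minTract = 200L,
                             maxGap = 24L, minPurity = 0.8,
                             seqId = "seq", motifSet = NULL) {
    stopifnot(nchar(motif) == 6L, minTract >= 6L, maxGap >= 0L,
              minPurity > 0, minPurity <= 1)
    s <- .asDNA(seq)
    empty <- GRanges(seqnames = character(0), ranges = IRanges(),
                     strand = character(0),
                     unit_count = integer(0), purity = numeric(0),
                     category = character(0))
    if (length(s) == 0L) return(empty)
    motifs <- unique(c(toupper(motif), toupper(motifSet)))
    out <- list()
    for (str in c("+", "-")) {
        occ <- integer(0)
        for (m in motifs) {
            pat <- if (str == "+") DNAString(m) else reverseComplement(DNAString(m))
            occ <- c(occ, BiocGenerics::start(matchPattern(pat, s, fixed = TRUE)))
        }
        if (!length(occ)) next
        occ <- sort(unique(occ))
        # greedy non-overlapping selection (motif copies are 6 bp)
        keep <- logical(length(occ)); lastEnd <- -1L
        for (i in seq_along(occ)) {
            if (occ[i] > lastEnd) { keep[i] <- TRUE; lastEnd <- occ[i] + 5L }
        }
        occ <- occ[keep]
        # chain occurrences with inter-occurrence gap <= maxGap
        gaps <- diff(occ) - 6L
        grp <- cumsum(c(0L, gaps > maxGap))
        for (g in split(occ, grp)) {
            st <- g[1L]; en <- g[length(g)] + 5L
            span <- en - st + 1L
            pur <- 6 * length(g) / span
            if (span >= minTract && pur >= minPurity)
                out[[length(out) + 1L]] <- data.frame(
                    start = st, end = en, strand = str,
                    unit_count = length(g), purity = pur)
        }
    }
    if (!length(out)) return(empty)
    df <- do.call(rbind, out)
    gr <- GRanges(seqId, IRanges(df$start, df$end), strand = df$strand,
                  unit_count = df$unit_count, purity = df$purity,
                  category = NA_character_)
    # merge overlapping same-strand candidates (possible only with motifSet
    # variants whose occurrences interleave)
    gr <- .mergeSameStrand(gr)
    gr[order(BiocGenerics::start(gr), as.character(BiocGenerics::strand(gr)))]
}

.mergeSameStrand <- function(gr) {
    if (length(gr) < 2L) return(gr)
    keep <- list()
    for (str in c("+", "-")) {
        g <- gr[BiocGenerics::strand(gr) == str]
        if (length(g) < 2L) { keep[[str]] <- g; next }
        g <- g[order(BiocGenerics::start(g))]
        red <- GenomicRanges::reduce(g)
        hit <- GenomicRanges::findOverlaps(g, red)
        uc <- tapply(g$unit_count, S4Vectors::subjectHits(hit), sum)
        m <- red
        m$unit_count <- as.integer(uc)
        m$purity <- pmin(1, 6 * m$unit_count / BiocGenerics::width(m))
        m$category <- NA_character_
        keep[[str]] <- m
    }
    BiocGenerics::sort(do.call(c, unname(keep)), ignore.strand = TRUE)
}

#' Classify tracts as terminal or interstitial
#'
#' For each sequence, the tract closest to coordinate 1 is `terminal_p` if
#' it starts within `endWindow` bp of the sequence start; the tract
#' closest to the sequence end is `terminal_q` if it ends within
#' `endWindow` bp of it; all others are `interstitial`. A tract
#' qualifying for both ends (short sequences) is assigned the nearer end.
#' Ties in "closest to the end" are broken in favour of the longer tract.
#'
#' @param tracts `GRanges` from [findRepeatTracts()] (one or more
#'   sequences).
#' @param seqLengths named integer vector of sequence lengths.
#' @param endWindow distance from a sequence end (bp) within which a tract
#'   can be terminal; default 100000 (the window used to define
#'   chromosome-end TERRA territory).
#' @return `tracts` with the `category` metadata column filled in.
#' @export
classifyTracts <- function(tracts, seqLengths, endWindow = 100000L) {
    stopifnot(endWindow > 0L)
    if (length(tracts) == 0L) return(tracts)
    sq <- as.character(GenomeInfoDb::seqnames(tracts))
    if (!all(sq %in% names(seqLengths)))
        stop("seqLengths missing entries for: ",
             paste(setdiff(sq, names(seqLengths)), collapse = ", "))
    if (any(BiocGenerics::end(tracts) > seqLengths[sq]))
        stop("tract extends past its sequence length")
    cat <- rep("interstitial", length(tracts))
    for (sid in unique(sq)) {
        idx <- which(sq == sid)
        L <- seqLengths[[sid]]
        st <- BiocGenerics::start(tracts)[idx]
        en <- BiocGenerics::end(tracts)[idx]
        w <- en - st + 1L
        d0 <- st - 1L
        d1 <- L - en
        # closest tract to each end; ties -> longer tract
        pOrd <- idx[order(d0, -w)]
        qOrd <- idx[order(d1, -w)]
        pCand <- pOrd[1L]; qCand <- qOrd[1L]
        pOK <- BiocGenerics::start(tracts)[pCand] - 1L < endWindow
        qOK <- L - BiocGenerics::end(tracts)[qCand] < endWindow
        if (pOK && qOK && pCand == qCand) {
            # one tract nearest to both ends: assign the nearer end (tie -> p)
            if (L - BiocGenerics::end(tracts)[pCand] <
                BiocGenerics::start(tracts)[pCand] - 1L)
                cat[pCand] <- "terminal_q" else cat[pCand] <- "terminal_p"
        } else {
            if (pOK) cat[pCand] <- "terminal_p"
            if (qOK) cat[qCand] <- "terminal_q"
        }
    }
    tracts$category <- cat
    tracts
}

#' Scan a genome assembly for telomeric repeat tracts
#'
#' Applies [findRepeatTracts()] to every record of a `DNAStringSet` (or a
#' FASTA file) and classifies the tracts with [classifyTracts()].
#'
#' @param genome a `DNAStringSet` or path to a FASTA file.
#' @param endWindow see [classifyTracts()].
#' @inheritParams findRepeatTracts
#' @return A `GRanges` of classified tracts across all sequences.
#' @export
scanGenome <- function(genome, motif = "TTAGGG", minTract = 200L,
                       maxGap = 24L, minPurity = 0.8,
                       endWindow = 100000L, motifSet = NULL) {
    if (is.character(genome) && length(genome) == 1L && file.exists(genome))
        genome <- readDNAStringSet(genome)
    stopifnot(is(genome, "DNAStringSet"))
    ids <- names(genome)
    if (is.null(ids)) ids <- paste0("seq", seq_along(genome))
    ids <- sub("\\s.*$", "", ids)
    res <- lapply(seq_along(genome), function(i)
        findRepeatTracts(genome[[i]], motif = motif, minTract = minTract,
                         maxGap = maxGap, minPurity = minPurity,
                         seqId = ids[i], motifSet = motifSet))
    gr <- suppressWarnings(do.call(c, res))
    classifyTracts(gr, setNames(BiocGenerics::width(genome), ids),
                   endWindow = endWindow)
}

#' Measure bulk and telomeric tract length of a read
#'
#' For a (long) RNA read given 5'->3' as DNA, reports the read length, the
#' span of the longest G-rich (`UUAGGG`-orientation) telomeric tract
#' detected with error-tolerant chaining, and whether that tract reaches
#' the read's 3' terminus. Defaults (`maxGap = 48`, `minPurity = 0.5`)
#' tolerate Nanopore-scale indel/substitution error while rejecting chance
#' hexamer hits; `minTract = 24` (four clean motif copies) is the floor
#' for calling a tract in a read at all.
#'
#' @param read a `DNAString` or character string (the read, sense strand).
#' @param motif repeat unit, default `TTAGGG`.
#' @param minTract,maxGap,minPurity chaining parameters (read-tuned
#'   defaults).
#' @param threePrimeMargin bp from the 3' end within which the tract must
#'   end to be flagged `telo_touches_3prime` (default 30).
#' @param motifSet optional extra motif variants.
#' @return A list with `bulk_len`, `telo_len` (0 if no tract) and
#'   `telo_touches_3prime`.
#' @examples
#' r <- paste0(strrep("ACGT", 125), strrep("TTAGGG", 50))
#' measureReadTract(r)   # bulk 800, telo 300, touches 3' TRUE
#' @export
measureReadTract <- function(read, motif = "TTAGGG", minTract = 24L,
                             maxGap = 48L, minPurity = 0.5,
                             threePrimeMargin = 30L, motifSet = NULL) {
    s <- .asDNA(read, "read")
    if (length(s) == 0L) stop("read is empty", call. = FALSE)
    tr <- findRepeatTracts(s, motif = motif, minTract = minTract,
                           maxGap = maxGap, minPurity = minPurity,
                           motifSet = motifSet)
    tr <- tr[BiocGenerics::strand(tr) == "+"]   # G-rich orientation only
    if (length(tr) == 0L)
        return(list(bulk_len = length(s), telo_len = 0L,
                    telo_touches_3prime = FALSE))
    best <- tr[which.max(BiocGenerics::width(tr))]
    list(bulk_len = length(s),
         telo_len = BiocGenerics::width(best),
         telo_touches_3prime =
             length(s) - BiocGenerics::end(best) <= threePrimeMargin)
}

#' Measure tract lengths for a set of reads
#'
#' @param reads a `DNAStringSet` or path to a FASTA file of reads.
#' @inheritParams measureReadTract
#' @return A data.frame with columns `read_id`, `bulk_len`, `telo_len`,
#'   `telo_touches_3prime`.
#' @export
measureReadTracts <- function(reads, motif = "TTAGGG", minTract = 24L,
                              maxGap = 48L, minPurity = 0.5,
                              threePrimeMargin = 30L, motifSet = NULL) {
    if (is.character(reads) && length(reads) == 1L && file.exists(reads))
        reads <- readDNAStringSet(reads)
    stopifnot(is(reads, "DNAStringSet"))
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    res <- lapply(seq_along(reads), function(i)
        measureReadTract(reads[[i]], motif = motif, minTract = minTract,
                         maxGap = maxGap, minPurity = minPurity,
                         threePrimeMargin = threePrimeMargin,
                         motifSet = motifSet))
    data.frame(read_id = ids,
               bulk_len = vapply(res, `[[`, integer(1), "bulk_len"),
               telo_len = vapply(res, `[[`, integer(1), "telo_len"),
               telo_touches_3prime = vapply(res, `[[`, logical(1),
                                            "telo_touches_3prime"),
               stringsAsFactors = FALSE)
}

#' Filter long-read alignments to unique reads
#'
#' Keeps records with MAPQ >= 1 whose FLAG is one of 0, 16, 2048 or 2064
#' (primary or supplementary, forward or reverse; unpaired, non-secondary,
#' non-duplicate). Then, per read id, supplementary records are dropped
#' whenever a primary record for the same read survives, and if several
#' records still remain for one read the highest-MAPQ one (first on tie)
#' is kept, so at most one record per read id is returned. The operation
#' is idempotent.
#'
#' @param aln alignment data.frame with columns `read_id`, `seq_id`,
#'   `start`, `end`, `mapq`, `flag` (see [readAlignments()]).
#' @return The filtered alignment data.frame.
#' @export
filterLongReadAlignments <- function(aln) {
    if (NROW(aln) == 0L) return(.emptyAlignments())
    aln <- .checkAlignments(aln)
    fl <- as.integer(aln$flag)
    keep <- aln$mapq >= 1L &
        bitwAnd(fl, bitwNot(bitwOr(.FLAG_REVERSE, .FLAG_SUPPL))) == 0L
    aln <- aln[keep, , drop = FALSE]
    if (NROW(aln) == 0L) return(aln)
    suppl <- bitwAnd(as.integer(aln$flag), .FLAG_SUPPL) != 0L
    hasPrimary <- tapply(!suppl, aln$read_id, any)
    drop <- suppl & hasPrimary[aln$read_id]
    aln <- aln[!drop, , drop = FALSE]
    ord <- order(bitwAnd(as.integer(aln$flag), .FLAG_SUPPL) != 0L,
                 -aln$mapq)
    aln <- aln[ord, , drop = FALSE]
    aln <- aln[!duplicated(aln$read_id), , drop = FALSE]
    aln[order(aln$seq_id, aln$start), , drop = FALSE]
}
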