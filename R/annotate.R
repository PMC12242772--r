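#' Binned coverage from alignments
#'
#' Counts alignment records overlapping each bin of a fixed grid (bin
#' size 30 bp by default, matching common coverage-track practice) and
#' optionally rescales to RPKM or CPM.
#'
#' @param aln alignment data.frame (columns `seq_id`, `start`, `end`, ...).
#' @param seqId,seqLen the sequence to cover.
#' @param binSize bin width in bp.
#' @param normalization `"raw"`, `"RPKM"` (reads per kb of bin per million
#'   mapped reads) or `"CPM"`.
#' @param librarySize total mapped records for the sample; required for
#'   RPKM/CPM, defaults to `nrow(aln)`.
#' @return A [CoverageTrack-class].
#' @export
coverageFromAlignments <- function(aln, seqId, seqLen, binSize = 30L,
                                   normalization = c("raw", "RPKM", "CPM"),
                                   librarySize = NULL) {
    normalization <- match.arg(normalization)
    if (is.null(librarySize)) librarySize <- NROW(aln)
    nb <- as.integer(ceiling(seqLen / binSize))
    counts <- numeric(nb)
    a <- aln[aln$seq_id == seqId, , drop = FALSE]
    if (NROW(a)) {
        b1 <- pmax(1L, (as.integer(a$start) - 1L) %/% binSize + 1L)
        b2 <- pmin(nb, (as.integer(a$end) - 1L) %/% binSize + 1L)
        for (i in seq_len(NROW(a)))
            counts[b1[i]:b2[i]] <- counts[b1[i]:b2[i]] + 1
    }
    v <- switch(normalization,
        raw = counts,
        CPM = counts * 1e6 / max(1, librarySize),
        RPKM = counts * 1e9 / (max(1, librarySize) * binSize))
    coverageTrack(seqId, seqLen, v, binSize = binSize,
                  normalization = normalization)
}

#' Per-bin log2 enrichment of capture over control
#'
#' Computes `log2((capture + p) / (control + p))` bin by bin, the standard
#' capture-versus-control comparison on matched coverage grids.
#'
#' @param capture,control [CoverageTrack-class] objects on the same
#'   sequence with identical bin grids.
#' @param pseudocount positive stabilizer `p` (default 1).
#' @return A `CoverageTrack` with `normalization = "log2ratio"`.
#' @examples
#' a <- coverageTrack("s", 90, c(4, 4, 4))
#' b <- coverageTrack("s", 90, c(1, 1, 1))
#' trackValues(log2Enrichment(a, b, pseudocount = 1e-6))  # ~2, 2, 2
#' @export
log2Enrichment <- function(capture, control, pseudocount = 1) {
    stopifnot(is(capture, "CoverageTrack"), is(control, "CoverageTrack"),
              pseudocount > 0)
    if (capture@seqId != control@seqId ||
        capture@binSize != control@binSize ||
        capture@seqLen != control@seqLen)
        stop("capture and control tracks are on different bin grids",
             call. = FALSE)
    v <- log2((capture@values + pseudocount) / (control@values + pseudocount))
    coverageTrack(capture@seqId, capture@seqLen, v,
                  binSize = capture@binSize, normalization = "log2ratio")
}

#' Cluster CAGE tags into TSS candidates
#'
#' Single-linkage clustering of same-strand tag positions: consecutive
#' sorted positions at most `window` bp apart join one cluster. The
#' cluster peak is the modal position; ties are broken toward the most 5'
#' position relative to the transcription direction (smallest coordinate
#' on `+`, largest on `-`).
#'
#' @param tags a `GRanges` of width-1 tag positions with strand, or a
#'   data.frame with columns `seq_id`, `position`, `strand`.
#' @param window linkage distance in bp (default 50).
#' @return A `GRanges` of width-1 cluster peaks with metadata column
#'   `tag_count`.
#' @export
clusterCageTags <- function(tags, window = 50L) {
    stopifnot(window > 0L)
    if (is.data.frame(tags))
        tags <- GRanges(tags$seq_id, IRanges(tags$position, width = 1L),
                        strand = tags$strand)
    if (length(tags) == 0L)
        return(GRanges(seqnames = character(0), ranges = IRanges(),
                       strand = character(0), tag_count = integer(0)))
    out <- list()
    sq <- as.character(GenomeInfoDb::seqnames(tags))
    strv <- as.character(BiocGenerics::strand(tags))
    for (key in unique(paste(sq, strv))) {
        i <- which(paste(sq, strv) == key)
        pos <- sort(BiocGenerics::start(tags)[i])
        grp <- cumsum(c(0L, diff(pos) > window))
        for (g in split(pos, grp)) {
            tab <- table(g)
            modal <- as.integer(names(tab)[tab == max(tab)])
            peak <- if (strv[i[1L]] == "+") min(modal) else max(modal)
            out[[length(out) + 1L]] <- data.frame(
                seq_id = sq[i[1L]], position = peak,
                strand = strv[i[1L]], tag_count = length(g))
        }
    }
    df <- do.call(rbind, out)
    gr <- GRanges(df$seq_id, IRanges(df$position, width = 1L),
                  strand = df$strand, tag_count = df$tag_count)
    BiocGenerics::sort(gr, ignore.strand = TRUE)
}

#' Classify a TERRA region by tract category and promoter signature
#'
#' Pure classification rule: interstitial tracts give Type III;
#' chromosome-end (terminal) tracts give Type I when at least one of the
#' 61/29/37 bp promoter element families is present in the promoter
#' signature, and Type II when the signature is empty.
#'
#' @param category tract category (`terminal_p`, `terminal_q`,
#'   `interstitial`).
#' @param signature logical vector `c(has61, has29, has37)` (see
#'   [promoterSignature()]).
#' @return `"I"`, `"II"` or `"III"`.
#' @export
classifyRegion <- function(category, signature) {
    stopifnot(category %in% c("terminal_p", "terminal_q", "interstitial"))
    if (category == "interstitial") return("III")
    if (any(as.logical(signature))) "I" else "II"
}

# enriched runs of consecutive qualifying bins within a coordinate window
# returns data.frame(startBp, endBp) per run (clipped to the window)
.enrichedRuns <- function(track, winStart, winEnd, threshold) {
    b <- track@binSize
    q <- track@values >= threshold
    b1 <- max(1L, (as.integer(winStart) - 1L) %/% b + 1L)
    b2 <- min(length(q), (as.integer(winEnd) - 1L) %/% b + 1L)
    if (b2 < b1) return(data.frame(startBp = integer(0), endBp = integer(0)))
    qq <- q[b1:b2]
    if (!any(qq)) return(data.frame(startBp = integer(0), endBp = integer(0)))
    r <- rle(qq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    i <- which(r$values)
    binSt <- b1 + starts[i] - 1L; binEn <- b1 + ends[i] - 1L
    data.frame(startBp = pmax(as.integer(winStart), (binSt - 1L) * b + 1L),
               endBp = pmin(as.integer(winEnd), binEn * b))
}

# pick the CAGE peak used as TSS: nearest to `anchor` within the window,
# ties preferring the upstream side; without an anchor, the
# highest-supported peak (tie -> most upstream)
.pickCage <- function(pos, counts, anchor, upstream) {
    if (!length(pos)) return(NA_integer_)
    if (is.na(anchor)) {
        best <- which(counts == max(counts))
        p <- pos[best]
        return(if (upstream < 0) min(p) else max(p))
    }
    d <- abs(pos - anchor)
    best <- which(d == min(d))
    if (length(best) > 1L) {
        up <- if (upstream < 0) pos[best] <= anchor else pos[best] >= anchor
        if (any(up)) best <- best[up]
    }
    pos[best[1L]]
}

.modalPos <- function(pos, upstream) {
    if (!length(pos)) return(NA_integer_)
    tab <- table(pos)
    modal <- as.integer(names(tab)[tab == max(tab)])
    if (upstream < 0) min(modal) else max(modal)
}

#' Call TERRA transcription regions from evidence tracks
#'
#' Turns the triple-evidence definition of TERRA transcription regions
#' into an algorithm. For every classified telomeric tract, the
#' `endWindow` adjacent to the tract on the transcription-upstream side
#' is searched for (i) a contiguous run of coverage-enrichment bins at or
#' above `enrThreshold` (log2 units) that reaches the tract, (ii)
#' long-read 5' ends and (iii) CAGE tag clusters. Arms with fewer than
#' `minEvidence` of the three evidence classes are reported as lacking
#' detectable TERRA (collected in `metadata(result)$no_terra`).
#'
#' The TSS is placed with precedence CAGE > long-read 5' ends > run
#' boundary: the CAGE cluster peak nearest the enriched run's inner
#' (telomere-distal) boundary, else the modal long-read 5' end in the
#' window, else the run boundary itself. The region spans TSS to the
#' distal edge of the tract; its subtelomeric part is the tract-free
#' interval and its telomeric part the tract. A second, telomere-distal
#' enriched run with its own CAGE or 5'-end support yields a second
#' region with `tss_rank = "distal"`. Interstitial tracts are processed
#' identically with the search window on the 5' flank implied by the
#' tract's G-rich orientation. Candidate regions narrower than
#' `minRegionWidth` bp are discarded as noise; regions are clipped to
#' sequence bounds.
#'
#' Strand convention: a q-arm region lies on the strand where `TTAGGG`
#' reads toward increasing coordinates (`+` for a q-terminal G-rich
#' tract), a p-arm region on the opposite strand; interstitial regions
#' take the G-rich tract orientation.
#'
#' @param tracts classified tract `GRanges` (see [classifyTracts()]).
#' @param seqLengths named vector of sequence lengths.
#' @param enrichment named list of log2-ratio [CoverageTrack-class]
#'   objects keyed by sequence name (may be `NULL`; regions can still be
#'   called from 5'-end + CAGE evidence when `minEvidence <= 2`).
#' @param fivePrimeEnds `GRanges` of width-1 long-read 5' end positions
#'   (stranded), or `NULL`.
#' @param cage `GRanges` of CAGE tag clusters from [clusterCageTags()],
#'   or `NULL`.
#' @param arrays promoter element arrays from [findAllElementArrays()]
#'   used for the promoter signature (may be empty).
#' @param endWindow search window adjacent to each tract, default 100000.
#' @param enrThreshold log2 enrichment cutoff, default 1 (2-fold).
#' @param minEvidence evidence classes required, default 2 of 3.
#' @param minRegionWidth minimum region span, default 200 bp.
#' @param promoterSize promoter window used for the signature, default
#'   3000 bp upstream of the TSS.
#' @return A [TerraRegions-class] object; arms without detectable TERRA
#'   are listed in `metadata()$no_terra`.
#' @export
callTerraRegions <- function(tracts, seqLengths, enrichment = NULL,
                             fivePrimeEnds = NULL, cage = NULL,
                             arrays = NULL, endWindow = 100000L,
                             enrThreshold = 1, minEvidence = 2L,
                             minRegionWidth = 200L, promoterSize = 3000L) {
    rows <- list(); noTerra <- character(0)
    sq <- as.character(GenomeInfoDb::seqnames(tracts))
    itsCounter <- integer(0)
    for (i in seq_along(tracts)) {
        sid <- sq[i]
        L <- as.integer(seqLengths[[sid]])
        tstart <- BiocGenerics::start(tracts)[i]
        tend <- BiocGenerics::end(tracts)[i]
        categ <- tracts$category[i]
        tStrand <- as.character(BiocGenerics::strand(tracts))[i]
        qLike <- switch(categ,
            terminal_q = TRUE, terminal_p = FALSE,
            interstitial = (tStrand == "+"))
        rStrand <- if (categ == "interstitial") tStrand
                   else if (qLike) "+" else "-"
        if (qLike) { wS <- max(1L, tstart - endWindow); wE <- tstart - 1L }
        else { wS <- tend + 1L; wE <- min(L, tend + endWindow) }
        label <- switch(categ,
            terminal_q = paste0(sid, "q"),
            terminal_p = paste0(sid, "p"),
            interstitial = {
                itsCounter[sid] <- if (is.na(itsCounter[sid])) 1L
                                   else itsCounter[sid] + 1L
                paste0("ITS_", sid, "_", itsCounter[sid])
            })
        if (wE < wS) { noTerra <- c(noTerra, label); next }
        upstream <- if (qLike) -1L else 1L

        track <- if (!is.null(enrichment)) enrichment[[sid]] else NULL
        runs <- if (is.null(track))
            data.frame(startBp = integer(0), endBp = integer(0))
        else .enrichedRuns(track, wS, wE, enrThreshold)
        bsz <- if (is.null(track)) 30L else track@binSize
        reach <- if (qLike) tstart - runs$endBp <= bsz + 1L
                 else runs$startBp - tend <= bsz + 1L
        proxRun <- if (any(reach)) runs[which(reach)[1L], ] else NULL

        fp <- if (is.null(fivePrimeEnds)) integer(0) else {
            sel <- as.character(GenomeInfoDb::seqnames(fivePrimeEnds)) == sid &
                as.character(BiocGenerics::strand(fivePrimeEnds)) == rStrand &
                BiocGenerics::start(fivePrimeEnds) >= wS &
                BiocGenerics::start(fivePrimeEnds) <= wE
            BiocGenerics::start(fivePrimeEnds)[sel]
        }
        cgSel <- if (is.null(cage)) NULL else {
            sel <- as.character(GenomeInfoDb::seqnames(cage)) == sid &
                as.character(BiocGenerics::strand(cage)) == rStrand &
                BiocGenerics::start(cage) >= wS &
                BiocGenerics::start(cage) <= wE
            list(pos = BiocGenerics::start(cage)[sel],
                 count = cage$tag_count[sel])
        }
        nEv <- sum(!is.null(proxRun), length(fp) > 0,
                   !is.null(cgSel) && length(cgSel$pos) > 0)
        if (nEv < minEvidence) { noTerra <- c(noTerra, label); next }

        anchor <- if (!is.null(proxRun)) {
            if (qLike) proxRun$startBp else proxRun$endBp
        } else NA_integer_
        tss <- NA_integer_
        if (!is.null(cgSel) && length(cgSel$pos))
            tss <- .pickCage(cgSel$pos, cgSel$count, anchor, upstream)
        if (is.na(tss) && length(fp)) tss <- .modalPos(fp, upstream)
        if (is.na(tss)) tss <- anchor
        tss <- min(max(tss, wS), wE)

        mkRow <- function(tssPos, rank, id) {
            if (qLike) {
                rs <- tssPos; re <- tend
                sub <- c(tssPos, tstart - 1L); tel <- c(tstart, tend)
            } else {
                rs <- tstart; re <- tssPos
                sub <- c(tend + 1L, tssPos); tel <- c(tstart, tend)
            }
            if (sub[2L] < sub[1L] || re - rs + 1L < minRegionWidth) return(NULL)
            data.frame(region_id = id, seq_id = sid, start = rs, end = re,
                       strand = rStrand, tss = tssPos, tss_rank = rank,
                       subtel_start = sub[1L], subtel_end = sub[2L],
                       telo_start = tel[1L], telo_end = tel[2L],
                       tract_category = categ, stringsAsFactors = FALSE)
        }
        rows[[length(rows) + 1L]] <- mkRow(tss, "proximal", label)

        # second, telomere-distal run with its own TSS evidence
        if (categ != "interstitial" && NROW(runs) > 1L && !is.null(proxRun)) {
            distal <- runs[!reach, , drop = FALSE]
            if (NROW(distal)) {
                # farthest run from the telomere
                j <- if (qLike) which.min(distal$startBp)
                     else which.max(distal$endBp)
                dr <- distal[j, ]
                nearSt <- dr$startBp - 2L * bsz; nearEn <- dr$endBp + 2L * bsz
                dcg <- if (is.null(cgSel)) integer(0)
                       else cgSel$pos[cgSel$pos >= nearSt & cgSel$pos <= nearEn]
                dcgN <- if (is.null(cgSel)) integer(0)
                        else cgSel$count[cgSel$pos >= nearSt & cgSel$pos <= nearEn]
                dfp <- fp[fp >= nearSt & fp <= nearEn]
                if (length(dcg) || length(dfp)) {
                    dAnchor <- if (qLike) dr$startBp else dr$endBp
                    dtss <- if (length(dcg))
                        .pickCage(dcg, dcgN, dAnchor, upstream)
                    else .modalPos(dfp, upstream)
                    rows[[length(rows) + 1L]] <-
                        mkRow(dtss, "distal", paste0(label, "_distal"))
                }
            }
        }
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) {
        res <- terraRegions(GRanges(
            seqnames = character(0), ranges = IRanges(),
            strand = character(0),
            region_id = character(0), type = character(0), tss = integer(0),
            tss_rank = character(0), subtel_start = integer(0),
            subtel_end = integer(0), telo_start = integer(0),
            telo_end = integer(0), tract_category = character(0),
            has61 = logical(0), has29 = logical(0), has37 = logical(0)))
        metadata(res)$no_terra <- noTerra
        return(res)
    }
    df <- do.call(rbind, rows)
    sig <- t(vapply(seq_len(nrow(df)), function(r) {
        pw <- promoterWindow(df$seq_id[r], df$tss[r], df$strand[r],
                             size = promoterSize,
                             seqLen = seqLengths[[df$seq_id[r]]])
        if (is.null(arrays) || length(arrays) == 0L)
            c(has61 = FALSE, has29 = FALSE, has37 = FALSE)
        else promoterSignature(pw, arrays)
    }, logical(3)))
    df$has61 <- sig[, "has61"]; df$has29 <- sig[, "has29"]
    df$has37 <- sig[, "has37"]
    df$type <- vapply(seq_len(nrow(df)), function(r)
        classifyRegion(df$tract_category[r], sig[r, ]), character(1))
    df <- df[order(df$seq_id, df$start), , drop = FALSE]
    res <- terraRegions(df)
    metadata(res)$no_terra <- noTerra
    res
}
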