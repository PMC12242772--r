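#' Synthetic 61/29/37 bp promoter element consensuses
#'
#' The three subtelomeric repeat element families (61, 29 and 37 bp) that
#' mark TERRA promoters have no single published consensus usable as a
#' built-in; real scans should supply consensus sequences from a FASTA
#' file (records named `e61`, `e29`, `e37`). This function returns fixed
#' synthetic stand-in consensuses of the correct lengths, free of
#' telomeric `TTAGGG`/`CCCTAA` hexamers, so that the simulator and the
#' test-suite are fully self-contained. They are *synthetic*: they share
#' no sequence with the real element families.
#'
#' @return A `DNAStringSet` with records `e61` (61 bp), `e29` (29 bp),
#'   `e37` (37 bp).
#' @export
elementConsensuses <- function() {
    DNAStringSet(c(
        e61 = paste0("ACGTCCTGAATCGGATCATGCCTAGTCAGGAC",
                     "TTCAGATCCGGTATCACCGGAGTCAATGC"),
        e29 = "GATCCAGTCGCTAAGGTCATCGGACCTGA",
        e37 = "CCATGATCGTACGAGTTCGACCATGGTCTAAGCGATC"
    ))
}

#' Read element consensus sequences from FASTA
#'
#' @param path FASTA file with records named `e61`, `e29`, `e37` (name
#'   prefixes up to whitespace are used); lengths must match the names.
#' @return A `DNAStringSet` with those three records.
#' @export
readElementConsensuses <- function(path) {
    x <- readDNAStringSet(path)
    names(x) <- sub("\\s.*$", "", names(x))
    need <- c(e61 = 61L, e29 = 29L, e37 = 37L)
    missing <- setdiff(names(need), names(x))
    if (length(missing))
        stop("consensus FASTA lacks records: ", paste(missing, collapse = ", "))
    x <- x[names(need)]
    if (!all(BiocGenerics::width(x) == need))
        stop("consensus lengths must be 61/29/37 bp to match their names")
    x
}

# best-identity, non-overlapping selection of candidate hits
.collapseHits <- function(st, en, ident) {
    ord <- order(-ident, st)
    keep <- logical(length(st))
    covSt <- integer(0); covEn <- integer(0)
    for (i in ord) {
        if (!any(st[i] <= covEn & en[i] >= covSt)) {
            keep[i] <- TRUE
            covSt <- c(covSt, st[i]); covEn <- c(covEn, en[i])
        }
    }
    which(keep)
}

#' Find tandem arrays of a promoter element
#'
#' Slides an element consensus over both strands of a sequence with a
#' similarity search allowing substitutions and single-base indels (edit
#' distance at most `floor((1 - minIdentity) * length(consensus))`).
#' Overlapping candidate hits are resolved best-identity-first; surviving
#' hits whose starts lie within `1.5 x` the element length of the
#' previous hit's start are chained into a tandem array. Arrays with at
#' least `minCopies` copies are returned. Overlapping arrays of different
#' elements are all reported (no mutual exclusion).
#'
#' @param seq a `DNAString` or character string to scan.
#' @param consensus a `DNAString`/character consensus sequence.
#' @param element element name recorded in the output (`e61`/`e29`/`e37`
#'   or any label).
#' @param minCopies minimum copies per array (default 2).
#' @param minIdentity minimum per-copy identity, default 0.8 (subtelomeric
#'   elements diverge between chromosome arms).
#' @param seqId sequence name for the output.
#' @return A `GRanges` with metadata columns `element_name`, `copies`,
#'   `mean_identity`, sorted by start.
#' @examples
#' cons <- elementConsensuses()[["e37"]]
#' arr <- findElementArrays(strrep(as.character(cons), 5), cons, "e37")
#' arr$copies   # 5
#' @export
findElementArrays <- function(seq, consensus, element = "element",
                              minCopies = 2L, minIdentity = 0.8,
                              seqId = "seq") {
    stopifnot(minCopies >= 1L, minIdentity > 0, minIdentity <= 1)
    s <- .asDNA(seq)
    cons <- .asDNA(consensus, "consensus")
    L <- length(cons)
    empty <- GRanges(seqnames = character(0), ranges = IRanges(),
                     strand = character(0), element_name = character(0),
                     copies = integer(0), mean_identity = numeric(0))
    if (length(s) < L) return(empty)
    k <- floor((1 - minIdentity) * L)
    consChr <- as.character(cons)
    out <- list()
    for (str in c("+", "-")) {
        pat <- if (str == "+") cons else reverseComplement(cons)
        patChr <- as.character(pat)
        m <- matchPattern(pat, s, max.mismatch = k, with.indels = TRUE,
                          fixed = TRUE)
        if (length(m) == 0L) next
        st <- BiocGenerics::start(m); en <- BiocGenerics::end(m)
        hits <- as.character(m)
        dist <- as.integer(utils::adist(hits, patChr))
        ident <- 1 - dist / L
        ok <- ident >= minIdentity
        st <- st[ok]; en <- en[ok]; ident <- ident[ok]
        if (!length(st)) next
        sel <- .collapseHits(st, en, ident)
        ord <- sel[order(st[sel])]
        st <- st[ord]; en <- en[ord]; ident <- ident[ord]
        # chain: start-to-start spacing of consecutive copies <= 1.5 L
        grp <- cumsum(c(0L, diff(st) > 1.5 * L))
        for (g in unique(grp)) {
            i <- which(grp == g)
            if (length(i) < minCopies) next
            out[[length(out) + 1L]] <- data.frame(
                start = st[i[1L]], end = en[i[length(i)]], strand = str,
                element_name = element, copies = length(i),
                mean_identity = mean(ident[i]))
        }
    }
    if (!length(out)) return(empty)
    df <- do.call(rbind, out)
    gr <- GRanges(seqId, IRanges(df$start, df$end), strand = df$strand,
                  element_name = df$element_name, copies = as.integer(df$copies),
                  mean_identity = df$mean_identity)
    gr[order(BiocGenerics::start(gr))]
}

#' Find arrays of all three promoter elements across a genome
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param consensuses `DNAStringSet` with records `e61`, `e29`, `e37`
#'   (e.g. [readElementConsensuses()] or, for simulations,
#'   [elementConsensuses()]).
#' @inheritParams findElementArrays
#' @return Combined `GRanges` of arrays for all elements and sequences.
#' @export
findAllElementArrays <- function(genome, consensuses = elementConsensuses(),
                                 minCopies = 2L, minIdentity = 0.8) {
    if (is.character(genome) && length(genome) == 1L && file.exists(genome))
        genome <- readDNAStringSet(genome)
    stopifnot(is(genome, "DNAStringSet"))
    ids <- sub("\\s.*$", "", names(genome))
    res <- list()
    for (i in seq_along(genome))
        for (el in names(consensuses))
            res[[length(res) + 1L]] <- findElementArrays(
                genome[[i]], consensuses[[el]], element = el,
                minCopies = minCopies, minIdentity = minIdentity,
                seqId = ids[i])
    gr <- suppressWarnings(do.call(c, res))
    gr[order(as.character(GenomeInfoDb::seqnames(gr)), BiocGenerics::start(gr))]
}

#' Promoter-element signature of a promoter window
#'
#' Scores which of the three element families overlap a promoter interval
#' (conventionally the 3 kb window upstream of a TSS, oriented with the
#' region's transcription direction) by at least 1 bp. Not all Type I
#' promoters carry all three families; any non-empty signature supports
#' Type I classification.
#'
#' @param promoter a `GRanges` of length 1 (the promoter window).
#' @param arrays element arrays from [findElementArrays()] /
#'   [findAllElementArrays()].
#' @return Named logical vector `c(has61, has29, has37)`.
#' @export
promoterSignature <- function(promoter, arrays) {
    stopifnot(is(promoter, "GRanges"), length(promoter) == 1L)
    sig <- c(has61 = FALSE, has29 = FALSE, has37 = FALSE)
    if (length(arrays) == 0L) return(sig)
    ov <- suppressWarnings(
        GenomicRanges::findOverlaps(promoter, arrays, ignore.strand = TRUE))
    hit <- arrays$element_name[S4Vectors::subjectHits(ov)]
    sig["has61"] <- "e61" %in% hit
    sig["has29"] <- "e29" %in% hit
    sig["has37"] <- "e37" %in% hit
    sig
}

#' Promoter window upstream of a TSS
#'
#' @param seqId sequence name.
#' @param tss TSS coordinate (1-based).
#' @param strand transcription strand: `"+"` puts the window on
#'   `[tss - size, tss - 1]`, `"-"` on `[tss + 1, tss + size]`.
#' @param size window size in bp (default 3000, the conventional promoter
#'   window upstream of TERRA TSSs).
#' @param seqLen optional sequence length for clipping.
#' @return A `GRanges` of length 1.
#' @export
promoterWindow <- function(seqId, tss, strand, size = 3000L, seqLen = NULL) {
    stopifnot(strand %in% c("+", "-"))
    if (strand == "+") { st <- tss - size; en <- tss - 1L }
    else { st <- tss + 1L; en <- tss + size }
    st <- max(1L, as.integer(st))
    if (!is.null(seqLen)) en <- min(as.integer(seqLen), as.integer(en))
    GRanges(seqId, IRanges(st, max(st, as.integer(en))), strand = strand)
}
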