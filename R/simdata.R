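.randomBases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

.defaultArms <- function() {
    list(
        list(name = "chrA", length = 400000L, side = "q", teloLen = 1998L,
             elements = c("e61", "e29", "e37"), subtelLen = 5000L,
             expression = 300),
        list(name = "chrB", length = 350000L, side = "q", teloLen = 1500L,
             elements = c("e61", "e37"), subtelLen = 4000L,
             expression = 250),
        list(name = "chrC", length = 500000L, side = "p", teloLen = 2502L,
             elements = c("e61", "e29", "e37"), subtelLen = 6000L,
             expression = 200),
        list(name = "chrD", length = 450000L, side = "q", teloLen = 1800L,
             elements = character(0), subtelLen = 5000L,
             expression = 220),
        list(name = "chrE", length = 300000L, side = "q", teloLen = 1998L,
             elements = character(0), subtelLen = 0L, expression = 0,
             its = list(list(pos = 150000L, tractLen = 402L,
                             subtelLen = 2500L, elements = "e37",
                             expression = 150))),
        list(name = "chrF", length = 320000L, side = "q", teloLen = 1602L,
             elements = character(0), subtelLen = 0L, expression = 0,
             its = list(list(pos = 160000L, tractLen = 300L,
                             subtelLen = 2000L, elements = "e37",
                             expression = 120)))
    )
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic TERRA data generator. The
#' default configuration is a six-arm mini-genome (arms 300-500 kb) with
#' three Type I regions of varying promoter composition (one lacking the
#' 29 bp element), one Type II region (no promoter elements), and two
#' expressed interstitial (Type III) regions whose promoters carry only
#' the 37 bp element — the composition typically seen at interstitial
#' TERRA promoters. Telomere tract and per-read tract lengths are kept
#' at multiples of the 6 bp repeat unit so that planted lengths coincide
#' with exact-motif tract boundaries.
#'
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @param arms list of arm descriptions; each a list with `name`,
#'   `length` (bp), `side` (`"q"`: telomere at the high-coordinate end,
#'   `"p"`: at coordinate 1), `teloLen`, `elements` (subset of
#'   e61/e29/e37 present at the promoter), `subtelLen` (length of the
#'   transcribed subtelomeric interval; 0 for unexpressed arms),
#'   `expression` (expected fragment count), and optionally `its`, a
#'   list of interstitial sites (`pos`, `tractLen`, `subtelLen`,
#'   `elements`, `expression`).
#' @param shortRead list: `readLen`, `fragMean`, `fragSd`,
#'   `backgroundPerKb` (capture-sample background fragments per kb),
#'   `controlPerKb` (control-sample fragments per kb), `lowMapqFrac`,
#'   `dupFrac`, `protocol` (`"none"` or `"forward"`).
#' @param longRead list: `nReads`, `tractRange` (bp, rounded to motif
#'   units), `subRate`, `insRate`, `delRate`, `tssJitterSd`.
#' @param cage list: `tagsPerTss`, `jitterSd`.
#' @param polya list: `defaultProb` and optionally `prob`, a named
#'   vector of per-region poly(A)+ probabilities.
#' @return A list of class `"SimConfig"`.
#' @export
simConfig <- function(seed = 1L, arms = .defaultArms(),
                      shortRead = list(), longRead = list(),
                      cage = list(), polya = list()) {
    sr <- utils::modifyList(list(readLen = 100L, fragMean = 300, fragSd = 50,
                                 backgroundPerKb = 0.2, controlPerKb = 0.5,
                                 lowMapqFrac = 0, dupFrac = 0,
                                 protocol = "none"), shortRead)
    lr <- utils::modifyList(list(nReads = 120L, tractRange = c(102L, 1500L),
                                 subRate = 0, insRate = 0, delRate = 0,
                                 tssJitterSd = 0), longRead)
    cg <- utils::modifyList(list(tagsPerTss = 50L, jitterSd = 5), cage)
    pa <- utils::modifyList(list(defaultProb = 0.5), polya)
    stopifnot(length(seed) == 1L, !is.na(seed),
              all(vapply(arms, function(a) a$length > 0, logical(1))),
              lr$subRate >= 0, lr$subRate < 1, lr$insRate >= 0,
              lr$insRate < 1, lr$delRate >= 0, lr$delRate < 1)
    for (a in arms) {
        stopifnot(a$side %in% c("p", "q"), a$teloLen > 0,
                  a$teloLen %% 6L == 0L)
        if (a$expression > 0 && a$subtelLen <= 0)
            stop("expressed arms need subtelLen > 0")
    }
    structure(list(seed = as.integer(seed), arms = arms, shortRead = sr,
                   longRead = lr, cage = cg, polya = pa),
              class = "SimConfig")
}

# lay the element arrays of one promoter into a bases vector ending at
# `promEnd`; arrays nearest the TSS first in the given order
.layPromoter <- function(bases, elements, promEnd, seqId, strand,
                         copies = 8L) {
    cons <- elementConsensuses()
    arrays <- list()
    at <- promEnd
    for (el in rev(elements)) {           # last listed element sits at TSS
        unit <- as.character(cons[[el]])
        if (strand == "-")
            unit <- as.character(reverseComplement(DNAString(unit)))
        arr <- strsplit(strrep(unit, copies), "")[[1L]]
        st <- at - length(arr) + 1L
        bases[st:at] <- arr
        arrays[[length(arrays) + 1L]] <- data.frame(
            seq_id = seqId, start = st, end = at, strand = strand,
            element = el, copies = copies, stringsAsFactors = FALSE)
        at <- st - 1L - 10L               # 10 bp spacer between arrays
    }
    list(bases = bases, arrays = do.call(rbind, arrays))
}

# remove chance telomeric hexamers outside planted tracts
.scrubMotif <- function(bases, tractStarts, tractEnds) {
    s <- paste(bases, collapse = "")
    for (iter in 1:12) {
        hits <- integer(0)
        for (m in c("TTAGGG", "CCCTAA"))
            hits <- c(hits, BiocGenerics::start(
                matchPattern(m, DNAString(s), fixed = TRUE)))
        if (length(tractStarts))
            hits <- hits[!vapply(hits, function(h)
                any(h + 5L >= tractStarts & h <= tractEnds), logical(1))]
        if (!length(hits)) break
        for (h in hits) {
            cur <- substr(s, h + 2L, h + 2L)
            repl <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
            substr(s, h + 2L, h + 2L) <- repl
        }
    }
    strsplit(s, "")[[1L]]
}

.flipCoord <- function(x, L) L - as.integer(x) + 1L
.flipInterval <- function(st, en, L) c(.flipCoord(en, L), .flipCoord(st, L))

#' Simulate a multi-arm mini-genome with ground truth
#'
#' Builds one FASTA record per configured arm: random background with a
#' terminal telomeric `TTAGGG` tract, promoter element arrays in the
#' 3 kb upstream of each planted TSS, a transcribed subtelomeric
#' interval, and optional interstitial telomeric sites with their own
#' promoters. Chance telomeric hexamers in the background are scrubbed
#' so planted tracts are the only ones present. `p`-side arms are built
#' telomere-last and then reverse-complemented, so their tracts read
#' `CCCTAA` on the forward strand and their regions run on `-`.
#'
#' @param cfg a [simConfig()] object.
#' @return A list with `genome` (`DNAStringSet`) and `truth`, a ledger
#'   holding `seqLengths`, planted `tracts`, `regions` (with expected
#'   expression levels), and element `arrays`.
#' @export
simulateGenome <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    seqs <- character(0)
    tracts <- list(); regions <- list(); arrays <- list()
    for (arm in cfg$arms) {
        L <- as.integer(arm$length)
        bases <- .randomBases(L)
        tStarts <- integer(0); tEnds <- integer(0)
        # terminal tract at the high end (q orientation during assembly)
        teloSt <- L - arm$teloLen + 1L
        bases[teloSt:L] <- strsplit(strrep("TTAGGG", arm$teloLen / 6L),
                                    "")[[1L]]
        tStarts <- c(tStarts, teloSt); tEnds <- c(tEnds, L)
        armRegions <- list(); armArrays <- list()
        termCat <- if (arm$side == "q") "terminal_q" else "terminal_p"
        if (arm$expression > 0) {
            tss <- teloSt - arm$subtelLen
            lay <- .layPromoter(bases, arm$elements, tss - 1L, arm$name, "+")
            bases <- lay$bases
            if (!is.null(lay$arrays))
                armArrays[[length(armArrays) + 1L]] <- lay$arrays
            armRegions[[length(armRegions) + 1L]] <- data.frame(
                region_id = paste0(arm$name, arm$side), seq_id = arm$name,
                start = tss, end = L, strand = "+", tss = tss,
                tss_rank = "proximal", subtel_start = tss,
                subtel_end = teloSt - 1L, telo_start = teloSt, telo_end = L,
                tract_category = termCat,
                has61 = "e61" %in% arm$elements,
                has29 = "e29" %in% arm$elements,
                has37 = "e37" %in% arm$elements,
                type = if (length(arm$elements)) "I" else "II",
                expression = arm$expression, stringsAsFactors = FALSE)
        }
        nIts <- 0L
        for (its in arm$its %||% list()) {
            nIts <- nIts + 1L
            tractLen <- (its$tractLen %/% 6L) * 6L
            iSt <- as.integer(its$pos); iEn <- iSt + tractLen - 1L
            bases[iSt:iEn] <- strsplit(strrep("TTAGGG", tractLen / 6L),
                                       "")[[1L]]
            tStarts <- c(tStarts, iSt); tEnds <- c(tEnds, iEn)
            if (its$expression > 0) {
                itss <- iSt - its$subtelLen
                lay <- .layPromoter(bases, its$elements, itss - 1L,
                                    arm$name, "+")
                bases <- lay$bases
                if (!is.null(lay$arrays))
                    armArrays[[length(armArrays) + 1L]] <- lay$arrays
                armRegions[[length(armRegions) + 1L]] <- data.frame(
                    region_id = paste0("ITS_", arm$name, "_", nIts),
                    seq_id = arm$name, start = itss, end = iEn,
                    strand = "+", tss = itss, tss_rank = "proximal",
                    subtel_start = itss, subtel_end = iSt - 1L,
                    telo_start = iSt, telo_end = iEn,
                    tract_category = "interstitial",
                    has61 = "e61" %in% its$elements,
                    has29 = "e29" %in% its$elements,
                    has37 = "e37" %in% its$elements,
                    type = "III", expression = its$expression,
                    stringsAsFactors = FALSE)
            }
        }
        bases <- .scrubMotif(bases, tStarts, tEnds)
        armTracts <- data.frame(
            seq_id = arm$name, start = tStarts, end = tEnds, strand = "+",
            category = c(termCat, rep("interstitial",
                                      length(tStarts) - 1L)),
            stringsAsFactors = FALSE)
        if (arm$side == "p") {
            bases <- rev(chartr("ACGT", "TGCA", bases))
            flip <- function(df, cols) {
                for (cc in cols) {
                    newSt <- .flipCoord(df[[cc[2L]]], L)
                    newEn <- .flipCoord(df[[cc[1L]]], L)
                    df[[cc[1L]]] <- newSt; df[[cc[2L]]] <- newEn
                }
                df
            }
            armTracts <- flip(armTracts, list(c("start", "end")))
            armTracts$strand <- ifelse(armTracts$strand == "+", "-", "+")
            if (length(armRegions)) {
                r <- do.call(rbind, armRegions)
                r <- flip(r, list(c("start", "end"),
                                  c("subtel_start", "subtel_end"),
                                  c("telo_start", "telo_end")))
                r$tss <- .flipCoord(r$tss, L)
                r$strand <- "-"
                armRegions <- list(r)
            }
            if (length(armArrays)) {
                a <- do.call(rbind, armArrays)
                a <- flip(a, list(c("start", "end")))
                a$strand <- ifelse(a$strand == "+", "-", "+")
                armArrays <- list(a)
            }
        }
        seqs[arm$name] <- paste(bases, collapse = "")
        tracts[[length(tracts) + 1L]] <- armTracts
        if (length(armRegions))
            regions[[length(regions) + 1L]] <- do.call(rbind, armRegions)
        if (length(armArrays))
            arrays[[length(arrays) + 1L]] <- do.call(rbind, armArrays)
    }
    genome <- DNAStringSet(seqs)
    truth <- list(
        seqLengths = setNames(BiocGenerics::width(genome), names(genome)),
        tracts = do.call(rbind, tracts),
        regions = do.call(rbind, regions),
        arrays = do.call(rbind, arrays))
    list(genome = genome, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw fragments within [lo, hi]; returns data.frame(start, end)
.drawFragments <- function(n, lo, hi, fragMean, fragSd) {
    if (n == 0L) return(data.frame(start = integer(0), end = integer(0)))
    fl <- pmin(hi - lo + 1L,
               pmax(60L, as.integer(round(rnorm(n, fragMean, fragSd)))))
    st <- lo + floor(runif(n) * (hi - lo + 2L - fl))
    data.frame(start = as.integer(st), end = as.integer(st + fl - 1L))
}

#' Simulate a short-read RNA-seq sample over the mini-genome
#'
#' Draws `Poisson(expression)` paired-end fragments per expressed region
#' (uniformly within the region) plus uniform genome-wide background, and
#' emits coordinate-sorted alignment records with SAM-conformant
#' FLAG/MAPQ fields directly from the generative coordinates (no aligner
#' is involved). Configurable fractions of low-MAPQ and flagged
#' duplicate records exercise the counting filters. A `"control"` sample
#' contains background fragments only, emulating non-captured RNA-seq.
#'
#' @param sim output of [simulateGenome()].
#' @param cfg the [simConfig()].
#' @param sample `"capture"` or `"control"`.
#' @param seed seed for this sample; defaults to `cfg$seed + 101`
#'   (capture) / `cfg$seed + 202` (control).
#' @return A list with `alignments` (record-level data.frame, two mates
#'   per fragment) and `reads` (per-fragment truth: `read_id`,
#'   `region_id` or `"background"`, coordinates).
#' @export
simulateShortReads <- function(sim, cfg, sample = c("capture", "control"),
                               seed = NULL) {
    sample <- match.arg(sample)
    stopifnot(inherits(cfg, "SimConfig"))
    if (is.null(seed))
        seed <- cfg$seed + if (sample == "capture") 101L else 202L
    set.seed(seed)
    sr <- cfg$shortRead
    truth <- sim$truth
    frags <- list()
    if (sample == "capture" && !is.null(truth$regions)) {
        for (r in seq_len(nrow(truth$regions))) {
            reg <- truth$regions[r, ]
            n <- rpois(1L, reg$expression)
            f <- .drawFragments(n, reg$start, reg$end, sr$fragMean, sr$fragSd)
            if (nrow(f))
                frags[[length(frags) + 1L]] <- cbind(
                    f, seq_id = reg$seq_id, region_id = reg$region_id,
                    reg_strand = reg$strand, stringsAsFactors = FALSE)
        }
    }
    rate <- if (sample == "capture") sr$backgroundPerKb else sr$controlPerKb
    totKb <- sum(truth$seqLengths) / 1000
    nBg <- rpois(1L, rate * totKb)
    if (nBg > 0L) {
        sid <- sample(names(truth$seqLengths), nBg, replace = TRUE,
                      prob = truth$seqLengths / sum(truth$seqLengths))
        for (sq in unique(sid)) {
            n <- sum(sid == sq)
            f <- .drawFragments(n, 1L, truth$seqLengths[[sq]] - 400L,
                                sr$fragMean, sr$fragSd)
            frags[[length(frags) + 1L]] <- cbind(
                f, seq_id = sq, region_id = "background",
                reg_strand = "+", stringsAsFactors = FALSE)
        }
    }
    if (!length(frags))
        return(list(alignments = .emptyAlignments(),
                    reads = data.frame(read_id = character(),
                                       region_id = character())))
    fr <- do.call(rbind, frags)
    fr$read_id <- sprintf("%s_frag%05d", sample, seq_len(nrow(fr)))
    fwd <- if (sr$protocol == "forward") fr$reg_strand == "+"
           else runif(nrow(fr)) < 0.5
    fr$mapq <- 60L
    nLow <- floor(sr$lowMapqFrac * nrow(fr))
    if (nLow > 0L) fr$mapq[sample.int(nrow(fr), nLow)] <- 10L
    mk <- function(fr, fw, dupFlag = 0L) {
        rl <- cfg$shortRead$readLen
        w <- pmin(rl, fr$end - fr$start + 1L)
        r1 <- data.frame(read_id = fr$read_id, seq_id = fr$seq_id,
                         start = fr$start, end = fr$start + w - 1L,
                         strand = ifelse(fw, "+", "-"),
                         mapq = fr$mapq,
                         flag = ifelse(fw, 99L, 83L) + dupFlag,
                         stringsAsFactors = FALSE)
        r2 <- data.frame(read_id = fr$read_id, seq_id = fr$seq_id,
                         start = fr$end - w + 1L, end = fr$end,
                         strand = ifelse(fw, "-", "+"),
                         mapq = fr$mapq,
                         flag = ifelse(fw, 147L, 163L) + dupFlag,
                         stringsAsFactors = FALSE)
        rbind(r1, r2)
    }
    aln <- mk(fr, fwd)
    nDup <- floor(sr$dupFrac * nrow(fr))
    if (nDup > 0L) {
        di <- sample.int(nrow(fr), nDup)
        dup <- fr[di, , drop = FALSE]
        dup$read_id <- paste0(dup$read_id, "_dup")
        dupAln <- mk(dup, fwd[di], dupFlag = 1024L)
        aln <- rbind(aln, dupAln)
    }
    aln$cigar <- paste0(aln$end - aln$start + 1L, "M")
    aln <- aln[order(aln$seq_id, aln$start), , drop = FALSE]
    rownames(aln) <- NULL
    list(alignments = aln,
         reads = fr[, c("read_id", "region_id", "seq_id", "start", "end")])
}

# corrupt a read with per-base substitution / insertion / deletion
.corruptRead <- function(seq, subRate, insRate, delRate) {
    if (subRate == 0 && insRate == 0 && delRate == 0) return(seq)
    b <- strsplit(seq, "")[[1L]]
    n <- length(b)
    u <- runif(n)
    del <- u < delRate
    sub <- !del & u < delRate + subRate
    if (any(sub)) {
        alt <- vapply(b[sub], function(x)
            sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
        b[sub] <- alt
    }
    ins <- runif(n) < insRate
    out <- character(0)
    pieces <- ifelse(del, "", b)
    insBase <- ifelse(ins, sample(c("A", "C", "G", "T"), n, TRUE), "")
    paste0(paste0(insBase, pieces), collapse = "")
}

#' Simulate long (direct RNA) reads with planted telomeric tracts
#'
#' Each read is drawn from an expressed chromosome-end region: a
#' subtelomeric prefix running from near the TSS to the telomere tract,
#' followed by a telomeric `TTAGGG` tract of a planted length (drawn
#' uniformly in `cfg$longRead$tractRange`, in whole motif units, capped
#' at the arm's telomere length), then corrupted by the configured
#' substitution/insertion/deletion process. The truth ledger records the
#' planted tract length and the genomic 5' end of every read. SAM-style
#' alignment records (primary, MAPQ 60; FLAG 16 on `-`-strand regions)
#' are emitted from the generative coordinates.
#'
#' @inheritParams simulateShortReads
#' @param seed defaults to `cfg$seed + 303`.
#' @return A list with `reads` (`DNAStringSet`), `alignments`
#'   (data.frame) and `truth` (per-read `region_id`, `planted_tract`,
#'   `fivep` genomic coordinate).
#' @export
simulateLongReads <- function(sim, cfg, seed = NULL) {
    stopifnot(inherits(cfg, "SimConfig"))
    if (is.null(seed)) seed <- cfg$seed + 303L
    set.seed(seed)
    lr <- cfg$longRead
    truth <- sim$truth
    regs <- truth$regions[truth$regions$expression > 0, , drop = FALSE]
    if (nrow(regs) == 0L) stop("no expressed TERRA regions")
    n <- lr$nReads
    pick <- sample.int(nrow(regs), n, replace = TRUE,
                       prob = regs$expression)
    lo <- (lr$tractRange[1L] %/% 6L) * 6L
    hi <- (lr$tractRange[2L] %/% 6L) * 6L
    tractLens <- sample(seq(lo, hi, by = 6L), n, replace = TRUE)
    seqsChr <- as.character(sim$genome)
    reads <- character(n); ids <- sprintf("lread%04d", seq_len(n))
    info <- vector("list", n)
    for (i in seq_len(n)) {
        reg <- regs[pick[i], ]
        teloLen <- reg$telo_end - reg$telo_start + 1L
        tl <- min(tractLens[i], teloLen)
        jit <- abs(as.integer(round(rnorm(1L, 0, lr$tssJitterSd))))
        if (reg$strand == "+") {
            fivep <- min(reg$tss + jit, reg$subtel_end)
            prefix <- substr(seqsChr[[reg$seq_id]], fivep, reg$subtel_end)
            spanSt <- fivep; spanEn <- reg$telo_start + tl - 1L
            flag <- 0L
        } else {
            fivep <- max(reg$tss - jit, reg$subtel_start)
            pref <- substr(seqsChr[[reg$seq_id]], reg$subtel_start, fivep)
            prefix <- as.character(reverseComplement(DNAString(pref)))
            spanSt <- reg$telo_end - tl + 1L; spanEn <- fivep
            flag <- 16L
        }
        clean <- paste0(prefix, strrep("TTAGGG", tl / 6L))
        reads[i] <- .corruptRead(clean, lr$subRate, lr$insRate, lr$delRate)
        info[[i]] <- data.frame(read_id = ids[i], region_id = reg$region_id,
                                seq_id = reg$seq_id, planted_tract = tl,
                                fivep = fivep, span_start = spanSt,
                                span_end = spanEn, strand = reg$strand,
                                flag = flag, stringsAsFactors = FALSE)
    }
    info <- do.call(rbind, info)
    aln <- data.frame(read_id = info$read_id, seq_id = info$seq_id,
                      start = info$span_start, end = info$span_end,
                      strand = info$strand, mapq = 60L, flag = info$flag,
                      cigar = paste0(info$span_end - info$span_start + 1L,
                                     "M"),
                      stringsAsFactors = FALSE)
    aln <- aln[order(aln$seq_id, aln$start), , drop = FALSE]
    rownames(aln) <- NULL
    rs <- DNAStringSet(setNames(reads, ids))
    list(reads = rs, alignments = aln, truth = info)
}

#' Simulate CAGE tags around planted TSSs
#'
#' Emits `tagsPerTss` 5' tags per expressed region, normally jittered
#' around the TSS (`jitterSd`), rounded and clipped to the arm, on the
#' region's transcription strand.
#'
#' @inheritParams simulateShortReads
#' @param seed defaults to `cfg$seed + 404`.
#' @return A `GRanges` of width-1 tag positions with strand.
#' @export
simulateCageTags <- function(sim, cfg, seed = NULL) {
    stopifnot(inherits(cfg, "SimConfig"))
    if (is.null(seed)) seed <- cfg$seed + 404L
    set.seed(seed)
    cg <- cfg$cage
    truth <- sim$truth
    out <- list()
    for (r in seq_len(NROW(truth$regions))) {
        reg <- truth$regions[r, ]
        pos <- as.integer(round(rnorm(cg$tagsPerTss, reg$tss, cg$jitterSd)))
        pos <- pmin(pmax(pos, 1L), truth$seqLengths[[reg$seq_id]])
        out[[r]] <- data.frame(seq_id = reg$seq_id, position = pos,
                               strand = reg$strand, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out)
    GRanges(df$seq_id, IRanges(df$position, width = 1L), strand = df$strand)
}

#' Split simulated reads into poly(A)+ and poly(A)- fractions
#'
#' Assigns each fragment to the poly(A)+ fraction with its region's
#' configured polyadenylation probability (background fragments with the
#' default probability); the complement goes to poly(A)-. Totals are
#' conserved.
#'
#' @param reads per-fragment truth table (from [simulateShortReads()]).
#' @param cfg the [simConfig()]; probabilities in `cfg$polya`.
#' @param seed defaults to `cfg$seed + 505`.
#' @return `reads` with an added `fraction` column (`"plus"`/`"minus"`).
#' @export
splitPolyaFractions <- function(reads, cfg, seed = NULL) {
    stopifnot(inherits(cfg, "SimConfig"))
    if (is.null(seed)) seed <- cfg$seed + 505L
    set.seed(seed)
    p <- rep(cfg$polya$defaultProb, nrow(reads))
    if (!is.null(cfg$polya$prob)) {
        hit <- match(reads$region_id, names(cfg$polya$prob))
        p[!is.na(hit)] <- cfg$polya$prob[hit[!is.na(hit)]]
    }
    reads$fraction <- ifelse(runif(nrow(reads)) < p, "plus", "minus")
    reads
}
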