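suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
    library(SummarizedExperiment)
})

# small 3-arm configuration used by module tests (fast to simulate)
tinyConfig <- function(seed = 1L, ...) {
    simConfig(seed = seed, arms = list(
        list(name = "chrT", length = 60000L, side = "q", teloLen = 600L,
             elements = c("e61", "e37"), subtelLen = 2000L,
             expression = 80),
        list(name = "chrU", length = 50000L, side = "p", teloLen = 450L,
             elements = character(0), subtelLen = 1500L, expression = 60),
        list(name = "chrV", length = 40000L, side = "q", teloLen = 600L,
             elements = character(0), subtelLen = 0L, expression = 0,
             its = list(list(pos = 20000L, tractLen = 300L,
                             subtelLen = 1000L, elements = "e37",
                             expression = 50)))
    ), ...)
}

# shared tiny simulation + evidence, built once per test run
tinyEvidence <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        cfg <- tinyConfig(seed = 42L)
        sim <- simulateGenome(cfg)
        cap <- simulateShortReads(sim, cfg, "capture")
        ctl <- simulateShortReads(sim, cfg, "control")
        sl <- sim$truth$seqLengths
        enr <- lapply(names(sl), function(sid) {
            a <- coverageFromAlignments(cap$alignments, sid, sl[[sid]],
                                        normalization = "RPKM",
                                        librarySize = nrow(cap$alignments))
            b <- coverageFromAlignments(ctl$alignments, sid, sl[[sid]],
                                        normalization = "RPKM",
                                        librarySize = nrow(ctl$alignments))
            log2Enrichment(a, b)
        })
        names(enr) <- names(sl)
        lr <- simulateLongReads(sim, cfg)
        fla <- filterLongReadAlignments(lr$alignments)
        fp <- GRanges(fla$seq_id,
                      IRanges(ifelse(fla$strand == "+", fla$start, fla$end),
                              width = 1L), strand = fla$strand)
        cage <- clusterCageTags(simulateCageTags(sim, cfg))
        cache <<- list(cfg = cfg, sim = sim, cap = cap, ctl = ctl,
                       enr = enr, lr = lr, fivep = fp, cage = cage,
                       endWindow = 5000L,   # scaled to the 40-60 kb arms
                       tracts = scanGenome(sim$genome, endWindow = 5000L),
                       arrays = findAllElementArrays(sim$genome))
        cache
    }
})

# ---------------------------------------------------------------------------
# brute-force oracle for tract chaining: O(n^2) enumeration of maximal
# occurrence chains under the gap rule, then span/purity filtering
oracleTracts <- function(seqChr, motif = "TTAGGG", minTract = 200L,
                         maxGap = 24L, minPurity = 0.8) {
    res <- list()
    for (str in c("+", "-")) {
        pat <- if (str == "+") motif
               else as.character(reverseComplement(DNAString(motif)))
        occ <- start(matchPattern(pat, DNAString(seqChr)))
        if (!length(occ)) next
        occ <- sort(occ)
        keep <- logical(length(occ)); lastEnd <- -1
        for (i in seq_along(occ))
            if (occ[i] > lastEnd) { keep[i] <- TRUE; lastEnd <- occ[i] + 5 }
        occ <- occ[keep]
        n <- length(occ)
        # chain i..j valid iff every consecutive gap <= maxGap; maximal
        # chains are delimited by gaps > maxGap
        breaks <- which(diff(occ) - 6L > maxGap)
        bounds <- cbind(c(1L, breaks + 1L), c(breaks, n))
        for (r in seq_len(nrow(bounds))) {
            i <- bounds[r, 1L]; j <- bounds[r, 2L]
            span <- occ[j] + 5L - occ[i] + 1L
            pur <- 6 * (j - i + 1L) / span
            if (span >= minTract && pur >= minPurity)
                res[[length(res) + 1L]] <- data.frame(
                    start = occ[i], end = occ[j] + 5L, strand = str,
                    unit_count = j - i + 1L, purity = pur)
        }
    }
    if (!length(res))
        return(data.frame(start = integer(), end = integer(),
                          strand = character(), unit_count = integer(),
                          purity = numeric()))
    df <- do.call(rbind, res)
    df[order(df$start, df$strand), , drop = FALSE]
}

tractsToDf <- function(gr) {
    if (length(gr) == 0L)
        return(data.frame(start = integer(), end = integer(),
                          strand = character(), unit_count = integer(),
                          purity = numeric()))
    data.frame(start = start(gr), end = end(gr),
               strand = as.character(strand(gr)),
               unit_count = gr$unit_count, purity = gr$purity,
               row.names = NULL)
}

# ---------------------------------------------------------------------------
# quadratic counting oracle: explicit per-fragment loops applying the
# mode's MAPQ/flag/duplicate/strand rules
oracleCounts <- function(aln, featDf, mode, libraryLayout = "paired",
                         strandedness = "none", dedup = "auto") {
    flag <- as.integer(aln$flag)
    secondary <- bitwAnd(flag, 256L) != 0L
    suppl <- bitwAnd(flag, 2048L) != 0L
    dup <- bitwAnd(flag, 1024L) != 0L
    first <- bitwAnd(flag, 64L) != 0L | bitwAnd(flag, 1L) == 0L
    if (mode == "arm_specific") {
        keep <- if (libraryLayout == "paired") aln$mapq >= 30 else
            aln$mapq == 255
    } else if (mode == "total") {
        keep <- !secondary & !suppl & aln$mapq >= 1
    } else keep <- aln$mapq >= 30
    a <- aln[keep, , drop = FALSE]
    dup <- dup[keep]; first <- first[keep]
    if (mode == "total" && nrow(a)) {
        useFlag <- if (dedup == "flag") TRUE
                   else if (dedup == "position") FALSE
                   else any(dup)                       # auto
        if (dedup != "none") {
            if (useFlag) {
                a <- a[!dup, , drop = FALSE]; first <- first[!dup]
            } else {
                key <- paste(a$seq_id, a$start, a$end, a$strand, first)
                sel <- !duplicated(key)
                a <- a[sel, , drop = FALSE]; first <- first[sel]
            }
        }
    }
    counts <- setNames(integer(nrow(featDf)), featDf$feature_id)
    if (!nrow(a)) return(counts)
    paired <- bitwAnd(as.integer(a$flag), 1L) != 0L
    frags <- list()
    if (libraryLayout == "paired" && any(paired)) {
        for (id in unique(a$read_id)) {
            idx <- which(a$read_id == id)
            fs <- idx[first[idx]]
            sidx <- if (length(fs)) fs[1L] else idx[1L]
            frags[[length(frags) + 1L]] <- list(
                seq = a$seq_id[idx[1L]], start = min(a$start[idx]),
                end = max(a$end[idx]), strand = a$strand[sidx])
        }
    } else {
        for (i in seq_len(nrow(a)))
            frags[[length(frags) + 1L]] <- list(
                seq = a$seq_id[i], start = a$start[i], end = a$end[i],
                strand = a$strand[i])
    }
    for (f in frags) {
        for (r in seq_len(nrow(featDf))) {
            ft <- featDf[r, ]
            if (f$seq != ft$seq_id) next
            if (f$end < ft$start || f$start > ft$end) next
            if (strandedness == "forward" && f$strand != ft$strand) next
            if (strandedness == "reverse" && f$strand == ft$strand) next
            counts[r] <- counts[r] + 1L
        }
    }
    counts
}

# build a small random TerraRegions object plus its mode feature tables
randomRegions <- function(nFeat, seqLen = 10000L) {
    n <- max(1L, nFeat %/% 2L)
    starts <- sort(sample.int(seqLen - 900L, n))
    rows <- lapply(seq_len(n), function(i) {
        st <- starts[i]
        w <- sample(200:800, 1L)
        en <- min(seqLen, st + w - 1L)
        split <- st + sample.int(w - 2L, 1L)
        type <- sample(c("I", "II", "III"), 1L)
        categ <- if (type == "III") "interstitial" else "terminal_q"
        data.frame(region_id = paste0("R", i), seq_id = "chrZ",
                   start = st, end = en, strand = sample(c("+", "-"), 1L),
                   tss = st, tss_rank = sample(c("proximal", "distal"), 1L),
                   subtel_start = st, subtel_end = split,
                   telo_start = split + 1L, telo_end = en,
                   tract_category = categ, type = type,
                   has61 = type == "I", has29 = FALSE,
                   has37 = type == "I", stringsAsFactors = FALSE)
    })
    terraRegions(do.call(rbind, rows))
}

# random alignment table: primary pairs with varied MAPQ and duplicate
# flags (coordinate-sorted)
randomAlignments <- function(nFrag, seqLen = 10000L, dupFrac = 0.1,
                             seqId = "chrZ") {
    st <- sample.int(seqLen - 500L, nFrag, replace = TRUE)
    fl <- sample(150:400, nFrag, replace = TRUE)
    en <- pmin(seqLen, st + fl - 1L)
    mapq <- sample(c(0L, 10L, 30L, 60L, 255L), nFrag, replace = TRUE)
    fwd <- runif(nFrag) < 0.5
    dup <- runif(nFrag) < dupFrac
    mk <- function(i) {
        w <- min(100L, en[i] - st[i] + 1L)
        dupBit <- if (dup[i]) 1024L else 0L
        rbind(
            data.frame(read_id = paste0("f", i), seq_id = seqId,
                       start = st[i], end = st[i] + w - 1L,
                       strand = if (fwd[i]) "+" else "-", mapq = mapq[i],
                       flag = (if (fwd[i]) 99L else 83L) + dupBit),
            data.frame(read_id = paste0("f", i), seq_id = seqId,
                       start = en[i] - w + 1L, end = en[i],
                       strand = if (fwd[i]) "-" else "+", mapq = mapq[i],
                       flag = (if (fwd[i]) 147L else 163L) + dupBit))
    }
    aln <- do.call(rbind, lapply(seq_len(nFrag), mk))
    aln[order(aln$seq_id, aln$start), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# independent step-by-step smooth-quantile oracle (explicit rank loops)
oracleQsmooth <- function(m, groups, windowFrac = 0.05) {
    n <- nrow(m); S <- ncol(m)
    groups <- as.character(groups)
    Q <- matrix(0, n, S)
    ords <- vector("list", S)
    for (s in 1:S) { ords[[s]] <- order(m[, s]); Q[, s] <- m[ords[[s]], s] }
    raw <- numeric(n)
    Qbar <- numeric(n)
    Qg <- matrix(0, n, length(unique(groups)))
    glev <- unique(groups)
    for (u in 1:n) {
        Qbar[u] <- mean(Q[u, ])
        sst <- sum((Q[u, ] - Qbar[u])^2)
        ssb <- 0
        for (gi in seq_along(glev)) {
            idx <- which(groups == glev[gi])
            Qg[u, gi] <- mean(Q[u, idx])
            ssb <- ssb + length(idx) * (Qg[u, gi] - Qbar[u])^2
        }
        raw[u] <- if (sst == 0) 1 else 1 - ssb / sst
    }
    k <- ceiling(windowFrac * n); if (k %% 2 == 0) k <- k + 1
    if (k >= n) k <- max(1, n - (1 - n %% 2))
    w <- if (k <= 1) raw else
        as.numeric(stats::runmed(raw, k, endrule = "constant"))
    w <- pmin(1, pmax(0, w))
    out <- m
    for (s in 1:S) {
        gi <- match(groups[s], glev)
        norm <- w * Qbar + (1 - w) * Qg[, gi]
        v <- numeric(n); v[ords[[s]]] <- norm
        v <- stats::ave(v, m[, s], FUN = mean)
        out[, s] <- v
    }
    out
}
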