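mkRegions <- function() {
    terraRegions(data.frame(
        region_id = c("Aq", "Bq"), seq_id = "chrZ",
        start = c(1000L, 5000L), end = c(2999L, 6999L), strand = "+",
        type = c("I", "II"), tss = c(1000L, 5000L), tss_rank = "proximal",
        subtel_start = c(1000L, 5000L), subtel_end = c(1999L, 5999L),
        telo_start = c(2000L, 6000L), telo_end = c(2999L, 6999L),
        tract_category = "terminal_q",
        has61 = c(TRUE, FALSE), has29 = FALSE, has37 = c(TRUE, FALSE)))
}

pairAln <- function(id, start, end, mapq = 60L, fwd = TRUE, dup = FALSE) {
    d <- if (dup) 1024L else 0L
    rbind(
        data.frame(read_id = id, seq_id = "chrZ", start = start,
                   end = start + 99L, strand = if (fwd) "+" else "-",
                   mapq = mapq, flag = (if (fwd) 99L else 83L) + d),
        data.frame(read_id = id, seq_id = "chrZ", start = end - 99L,
                   end = end, strand = if (fwd) "-" else "+",
                   mapq = mapq, flag = (if (fwd) 147L else 163L) + d))
}

sortAln <- function(a) a[order(a$seq_id, a$start), , drop = FALSE]

test_that("a fragment inside one region counts once for that feature", {
    regs <- mkRegions()
    aln <- sortAln(pairAln("f1", 1100L, 1500L))
    se <- countReads(aln, regs, mode = "total")
    counts <- assay(se, "counts")[, 1]
    expect_equal(unname(counts["Aq_subtel"]), 1L)
    expect_equal(sum(counts), 1L)
})

test_that("a fragment straddling two features counts in both", {
    regs <- mkRegions()
    aln <- sortAln(pairAln("f1", 1900L, 2200L))  # spans subtel/telo split
    counts <- assay(countReads(aln, regs, mode = "total"), "counts")[, 1]
    expect_equal(unname(counts["Aq_subtel"]), 1L)
    expect_equal(unname(counts["Aq_telo"]), 1L)
})

test_that("mode filters apply the documented MAPQ and flag rules", {
    regs <- mkRegions()
    aln <- sortAln(rbind(pairAln("hi", 1100L, 1500L, mapq = 60L),
                         pairAln("lo", 1150L, 1600L, mapq = 10L),
                         pairAln("z", 5100L, 5400L, mapq = 0L)))
    arm <- assay(countReads(aln, regs, mode = "arm_specific"), "counts")[, 1]
    expect_equal(unname(arm["Aq_subtel"]), 1L)       # MAPQ >= 30 only
    tot <- assay(countReads(aln, regs, mode = "total"), "counts")[, 1]
    expect_equal(unname(tot["Aq_subtel"]), 2L)       # MAPQ >= 1 keeps lo
    expect_equal(unname(tot["Bq_subtel"]), 0L)       # MAPQ 0 dropped
    cap <- assay(countReads(aln, regs, mode = "capture"), "counts")[, 1]
    expect_equal(unname(cap["Aq"]), 1L)
    # single-end uniqueness convention: MAPQ 255 only
    sing <- data.frame(read_id = c("s1", "s2"), seq_id = "chrZ",
                       start = c(1100L, 1200L), end = c(1199L, 1299L),
                       strand = "+", mapq = c(255L, 60L), flag = 0L)
    armS <- assay(countReads(sing, regs, mode = "arm_specific",
                             libraryLayout = "single"), "counts")[, 1]
    expect_equal(unname(armS["Aq_subtel"]), 1L)
})

test_that("flagged duplicates are removed in total mode", {
    regs <- mkRegions()
    aln <- sortAln(rbind(pairAln("f1", 1100L, 1500L),
                         pairAln("f1d", 1100L, 1500L, dup = TRUE)))
    tot <- assay(countReads(aln, regs, mode = "total", dedup = "flag"),
                 "counts")[, 1]
    expect_equal(unname(tot["Aq_subtel"]), 1L)
    # positional dedup collapses coordinate-identical fragments
    aln2 <- sortAln(rbind(pairAln("a", 1100L, 1500L),
                          pairAln("b", 1100L, 1500L),
                          pairAln("c", 1300L, 1700L)))
    tot2 <- assay(countReads(aln2, regs, mode = "total",
                             dedup = "position"), "counts")[, 1]
    expect_equal(unname(tot2["Aq_subtel"]), 2L)
})

test_that("strandedness constrains fragment orientation", {
    regs <- mkRegions()
    aln <- sortAln(rbind(pairAln("fw", 1100L, 1500L, fwd = TRUE),
                         pairAln("rv", 1200L, 1600L, fwd = FALSE)))
    fwd <- assay(countReads(aln, regs, mode = "total",
                            strandedness = "forward"), "counts")[, 1]
    expect_equal(unname(fwd["Aq_subtel"]), 1L)
    rev <- assay(countReads(aln, regs, mode = "total",
                            strandedness = "reverse"), "counts")[, 1]
    expect_equal(unname(rev["Aq_subtel"]), 1L)
    both <- assay(countReads(aln, regs, mode = "total"), "counts")[, 1]
    expect_equal(unname(both["Aq_subtel"]), 2L)
})

test_that("counting equals the brute-force overlap oracle on random inputs", {
    set.seed(2024)
    modes <- c("total", "arm_specific", "capture")
    for (rep in 1:20) {
        regs <- randomRegions(sample(2:10, 1))
        aln <- randomAlignments(sample(20:300, 1))
        mode <- modes[(rep - 1) %% 3 + 1]
        strd <- sample(c("none", "forward", "reverse"), 1)
        ddp <- sample(c("flag", "position", "none"), 1)
        se <- countReads(aln, regs, mode = mode, strandedness = strd,
                         dedup = ddp)
        featDf <- as.data.frame(rowData(se))
        want <- oracleCounts(aln, featDf, mode, "paired", strd, ddp)
        expect_equal(unname(assay(se, "counts")[, 1]), unname(want))
    }
})

test_that("counting is invariant to record order and dedup is idempotent", {
    set.seed(5)
    regs <- randomRegions(6)
    aln <- randomAlignments(100)
    base <- assay(countReads(aln, regs, mode = "total"), "counts")
    perm <- aln[sample(nrow(aln)), ]
    perm <- perm[order(perm$seq_id, perm$start), ]
    expect_equal(assay(countReads(perm, regs, mode = "total"), "counts"),
                 base)
    d1 <- terraseq:::.dedupRecords(aln, "position")
    expect_equal(terraseq:::.dedupRecords(d1, "position"), d1)
})

test_that("unsorted alignments are rejected and unknown sequences skipped", {
    regs <- mkRegions()
    aln <- pairAln("f1", 1100L, 1500L)[2:1, ]
    expect_error(countReads(aln, regs, mode = "total"), "sorted")
    odd <- data.frame(read_id = "x", seq_id = "chrQ", start = 1L,
                      end = 100L, strand = "+", mapq = 60L, flag = 0L)
    expect_warning(countReads(odd, regs, mode = "total"), "skipping")
})

test_that("simulated region fragment counts are recovered exactly", {
    ev <- tinyEvidence()
    regs <- terraRegions(ev$sim$truth$regions[
        , setdiff(colnames(ev$sim$truth$regions), "expression")])
    se <- countReads(ev$cap$alignments, regs, mode = "total",
                     dedup = "flag")
    got <- tapply(assay(se, "counts")[, 1],
                  rowData(se)$region_id, sum)
    # oracle from per-fragment truth: fragments count once per region
    # feature they overlap (boundary-straddlers count twice)
    truthReads <- ev$cap$reads
    want <- sapply(names(got), function(rid) {
        reg <- ev$sim$truth$regions[
            ev$sim$truth$regions$region_id == rid, ]
        onSeq <- truthReads$seq_id == reg$seq_id
        ovSub <- onSeq & truthReads$end >= reg$subtel_start &
            truthReads$start <= reg$subtel_end
        ovTel <- onSeq & truthReads$end >= reg$telo_start &
            truthReads$start <= reg$telo_end
        sum(ovSub) + sum(ovTel)
    })
    expect_equal(as.integer(got), as.integer(want))
})

test_that("total TERRA sums proximal Type I and II features only", {
    m <- matrix(c(5L, 7L, 3L, 100L), ncol = 1,
                dimnames = list(c("Isub", "Itel", "IIsub", "IIIsub"), "s1"))
    se <- SummarizedExperiment(
        assays = list(counts = m),
        rowData = S4Vectors::DataFrame(
            region_id = c("A", "A", "B", "C"),
            region_type = c("I", "I", "II", "III"),
            subregion = c("subtelomeric", "telomeric", "subtelomeric",
                          "subtelomeric"),
            tss_rank = "proximal"))
    expect_equal(unname(totalTerra(se)), 15)
    # distal TSS features are excluded too
    rowData(se)$tss_rank <- c("proximal", "proximal", "distal", "proximal")
    expect_equal(unname(totalTerra(se)), 12)
    onlyIII <- se[4, ]
    expect_equal(unname(totalTerra(onlyIII)), 0)
})

test_that("CPM scales by the whole-library size and is scale invariant", {
    m <- matrix(c(50, 0), ncol = 1)
    expect_equal(cpmMatrix(m, 1e6), matrix(c(50, 0), ncol = 1))
    set.seed(3)
    m2 <- matrix(rpois(20, 40), 5, 4)
    ls <- c(2e6, 1e6, 5e5, 3e6)
    expect_equal(cpmMatrix(2 * m2, 2 * ls), cpmMatrix(m2, ls))
})

test_that("poly(A) fractions, ratios and swaps follow their definitions", {
    p <- c(A = 20, B = 80)
    m <- c(A = 5, B = 95)
    res <- polyaEnrichment(p, m)
    expect_equal(res$frac_plus, c(0.2, 0.8))
    expect_equal(res$frac_minus, c(0.05, 0.95))
    expect_equal(res$log2_ratio[1], 2)           # 20%/5% -> ratio 4
    expect_equal(sum(res$frac_plus), 1, tolerance = 1e-9)
    expect_equal(sum(res$frac_minus), 1, tolerance = 1e-9)
    same <- polyaEnrichment(p, p)
    expect_true(all(same$log2_ratio == 0))
    swap <- polyaEnrichment(m, p)
    expect_equal(swap$log2_ratio, -res$log2_ratio)
    z <- c(A = 0, B = 10)
    flagged <- polyaEnrichment(z, m)
    expect_false(flagged$defined[1])
    expect_true(is.na(flagged$log2_ratio[1]))
    expect_error(polyaEnrichment(c(A = 0, B = 0), m), "zero total")
})

test_that("Pearson correlation matches the textbook formula", {
    x <- c(1, 2, 3, 4, 5)
    expect_equal(correlateRatios(x, x)$pearson_r, 1)
    expect_equal(correlateRatios(x, -x)$pearson_r, -1)
    set.seed(6)
    a <- rnorm(40); b <- 0.5 * a + rnorm(40)
    got <- correlateRatios(a, b)
    n <- 40
    r <- sum((a - mean(a)) * (b - mean(b))) /
        sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    expect_equal(got$pearson_r, r, tolerance = 1e-12)
    expect_equal(got$p_value, 2 * stats::pt(-abs(tstat), n - 2),
                 tolerance = 1e-12)
})
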