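test_that("log2 enrichment follows the per-bin formula", {
    a <- coverageTrack("s", 90, c(5, 2, 0))
    expect_equal(trackValues(log2Enrichment(a, a)), c(0, 0, 0))
    b <- coverageTrack("s", 90, c(4, 4, 4))
    d <- coverageTrack("s", 90, c(1, 1, 1))
    expect_equal(trackValues(log2Enrichment(b, d, pseudocount = 1e-9)),
                 rep(2, 3), tolerance = 1e-6)
    set.seed(2)
    x <- coverageTrack("s", 3000, runif(100, 0, 50))
    y <- coverageTrack("s", 3000, runif(100, 0, 50))
    got <- trackValues(log2Enrichment(x, y, pseudocount = 0.5))
    want <- log2((trackValues(x) + 0.5) / (trackValues(y) + 0.5))
    expect_equal(got, want, tolerance = 1e-9)
    expect_error(log2Enrichment(a, coverageTrack("s", 90, rep(0, 9),
                                                 binSize = 10)),
                 "grids")
})

test_that("coverage tracks enforce their bin-grid invariant", {
    expect_error(coverageTrack("s", 100, rep(0, 3), binSize = 30),
                 "bins")
    expect_error(coverageTrack("s", 100, c(0, 0, NA, 0), binSize = 30),
                 "finite")
    tr <- coverageTrack("s", 100, rep(1, 4), binSize = 30)
    expect_equal(length(tr), 4L)
    expect_equal(binSize(tr), 30L)
})

test_that("CAGE tags cluster by single linkage with modal peaks", {
    tags <- data.frame(seq_id = "c", position = rep(500L, 10),
                       strand = "+")
    cl <- clusterCageTags(tags)
    expect_length(cl, 1L)
    expect_equal(start(cl), 500L)
    expect_equal(cl$tag_count, 10L)
    two <- data.frame(seq_id = "c",
                      position = c(100L, 110L, 120L, 1100L, 1110L),
                      strand = "+")
    expect_length(clusterCageTags(two, window = 50), 2L)
    # modal tie resolves to the most 5' position for the strand
    tie <- data.frame(seq_id = "c", position = c(200L, 200L, 240L, 240L),
                      strand = c("-", "-", "-", "-"))
    expect_equal(start(clusterCageTags(tie)), 240L)
})

test_that("jittered simulated tags peak near the planted TSS", {
    ev <- tinyEvidence()
    truth <- ev$sim$truth$regions
    for (r in seq_len(nrow(truth))) {
        sel <- as.character(GenomeInfoDb::seqnames(ev$cage)) ==
            truth$seq_id[r] &
            abs(start(ev$cage) - truth$tss[r]) < 500
        expect_true(any(sel))
        expect_lte(min(abs(start(ev$cage)[sel] - truth$tss[r])), 50)
    }
})

test_that("region calling recovers planted regions, types and partitions", {
    ev <- tinyEvidence()
    regs <- callTerraRegions(ev$tracts, ev$sim$truth$seqLengths,
                             enrichment = ev$enr,
                             fivePrimeEnds = ev$fivep, cage = ev$cage,
                             arrays = ev$arrays, endWindow = ev$endWindow)
    truth <- ev$sim$truth$regions
    expect_equal(length(regs), nrow(truth))
    m <- match(regionId(regs), truth$region_id)
    expect_false(anyNA(m))
    expect_equal(regionType(regs), truth$type[m])
    expect_lte(max(abs(regionTss(regs) - truth$tss[m])), 50)
    mc <- S4Vectors::mcols(regs)
    expect_equal(mc$telo_start, truth$telo_start[m])
    expect_equal(mc$telo_end, truth$telo_end[m])
    # tract-side partition boundary is exact; the TSS-side boundary
    # moves with the (bounded) TSS error checked above
    plus <- as.character(strand(regs)) == "+"
    expect_equal(mc$subtel_end[plus], truth$subtel_end[m][plus])
    expect_equal(mc$subtel_start[!plus], truth$subtel_start[m][!plus])
    expect_equal(as.character(strand(regs)), truth$strand[m])
    # unexpressed arm ends are reported as TERRA-free
    expect_true("chrVq" %in% S4Vectors::metadata(regs)$no_terra)
})

test_that("arms with a tract but no evidence yield no region", {
    gr <- GRanges("bare", IRanges(99001, 100000), strand = "+",
                  unit_count = 166L, purity = 1,
                  category = "terminal_q")
    regs <- callTerraRegions(gr, c(bare = 100000L), enrichment = NULL,
                             fivePrimeEnds = NULL, cage = NULL)
    expect_length(regs, 0L)
    expect_equal(S4Vectors::metadata(regs)$no_terra, "bareq")
})

test_that("a telomere-distal enriched run with TSS support yields a second region", {
    sl <- c(dual = 200000L)
    tract <- GRanges("dual", IRanges(198001, 200000), strand = "+",
                     unit_count = 333L, purity = 1,
                     category = "terminal_q")
    # enrichment: proximal run reaching the tract (190-198 kb) and a
    # separate distal run (160-165 kb)
    v <- numeric(ceiling(200000 / 30))
    bins <- function(from, to) (((from - 1) %/% 30) + 1):(((to - 1) %/% 30) + 1)
    v[bins(190000, 198000)] <- 3
    v[bins(160000, 165000)] <- 3
    enr <- list(dual = coverageTrack("dual", 200000L, v,
                                     normalization = "log2ratio"))
    cage <- GRanges("dual", IRanges(c(189995, 159980), width = 1),
                    strand = "+", tag_count = c(40L, 25L))
    regs <- callTerraRegions(tract, sl, enrichment = enr, cage = cage,
                             minEvidence = 2L)
    expect_length(regs, 2L)
    mc <- S4Vectors::mcols(regs)
    expect_setequal(mc$tss_rank, c("proximal", "distal"))
    expect_equal(mc$tss[mc$tss_rank == "proximal"], 189995L)
    expect_equal(mc$tss[mc$tss_rank == "distal"], 159980L)
    # both regions end at the telomere's distal edge
    expect_equal(unique(end(regs)), 200000L)
})

test_that("dropping the CAGE track shifts the TSS but not the types", {
    ev <- tinyEvidence()
    with_cage <- callTerraRegions(ev$tracts, ev$sim$truth$seqLengths,
                                  enrichment = ev$enr,
                                  fivePrimeEnds = ev$fivep,
                                  cage = ev$cage, arrays = ev$arrays,
                                  endWindow = ev$endWindow)
    no_cage <- callTerraRegions(ev$tracts, ev$sim$truth$seqLengths,
                                enrichment = ev$enr,
                                fivePrimeEnds = ev$fivep, cage = NULL,
                                arrays = ev$arrays,
                                endWindow = ev$endWindow)
    expect_equal(length(with_cage), length(no_cage))
    m <- match(regionId(no_cage), regionId(with_cage))
    expect_equal(regionType(no_cage), regionType(with_cage)[m])
})

test_that("region classification is a pure mapping of category and signature", {
    expect_equal(classifyRegion("terminal_q", c(TRUE, TRUE, TRUE)), "I")
    expect_equal(classifyRegion("terminal_p", c(FALSE, FALSE, TRUE)), "I")
    expect_equal(classifyRegion("terminal_q", c(FALSE, FALSE, FALSE)), "II")
    expect_equal(classifyRegion("interstitial", c(TRUE, TRUE, TRUE)), "III")
    expect_equal(classifyRegion("interstitial", c(FALSE, FALSE, FALSE)),
                 "III")
    expect_error(classifyRegion("nonsense", c(TRUE, TRUE, TRUE)))
})

test_that("TerraRegions validity rejects inconsistent objects", {
    df <- data.frame(region_id = "r1", seq_id = "c", start = 100L,
                     end = 1000L, strand = "+", type = "I", tss = 100L,
                     tss_rank = "proximal", subtel_start = 100L,
                     subtel_end = 700L, telo_start = 701L,
                     telo_end = 1000L, tract_category = "terminal_q",
                     has61 = TRUE, has29 = FALSE, has37 = TRUE)
    expect_s4_class(terraRegions(df), "TerraRegions")
    bad <- df; bad$telo_start <- 650L           # overlapping sub-intervals
    expect_error(terraRegions(bad), "disjoint")
    bad2 <- df; bad2$type <- "III"              # type III on terminal tract
    expect_error(terraRegions(bad2), "interstitial")
    bad3 <- df; bad3$has61 <- FALSE; bad3$has37 <- FALSE  # type I, no elements
    expect_error(terraRegions(bad3), "promoter element")
})
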