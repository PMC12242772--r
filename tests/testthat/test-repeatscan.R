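test_that("pure tandem repeats give a single full-span tract", {
    tr <- findRepeatTracts(strrep("TTAGGG", 40), minTract = 200)
    expect_length(tr, 1L)
    expect_equal(start(tr), 1L)
    expect_equal(end(tr), 240L)
    expect_equal(as.character(strand(tr)), "+")
    expect_equal(tr$unit_count, 40L)
    expect_equal(tr$purity, 1)
})

test_that("sequences without the motif yield no tracts", {
    set.seed(5)
    s <- paste(sample(c("A", "C"), 1000, replace = TRUE), collapse = "")
    expect_length(findRepeatTracts(s), 0L)
    expect_length(findRepeatTracts(""), 0L)
})

test_that("tracts shorter than the minimum span are excluded", {
    # 198 bp pure tract (33 copies) under a 200 bp floor
    expect_length(findRepeatTracts(strrep("TTAGGG", 33), minTract = 200), 0L)
    expect_length(findRepeatTracts(strrep("TTAGGG", 34), minTract = 200), 1L)
})

test_that("an interrupted tract is chained across a small insert", {
    left <- strrep("TTAGGG", 25)              # 150 bp
    right <- strrep("TTAGGG", 25)
    s <- paste0(left, "GATCGATCGATC", right)  # 12 bp non-telomeric insert
    tr <- findRepeatTracts(s, minTract = 200, maxGap = 18, minPurity = 0.8)
    expect_length(tr, 1L)
    expect_equal(width(tr), 312L)
    expect_equal(tr$purity, 300 / 312)
    orc <- oracleTracts(s, minTract = 200, maxGap = 18, minPurity = 0.8)
    expect_equal(tractsToDf(tr), orc, ignore_attr = TRUE)
    # with a gap ceiling below the insert, the tract splits and both
    # halves fail the span filter
    expect_length(findRepeatTracts(s, minTract = 200, maxGap = 10), 0L)
})

test_that("rejects sequences with non-DNA characters", {
    expect_error(findRepeatTracts("TTAGGGRYTTAGGG"), "A/C/G/T/N")
    expect_silent(findRepeatTracts("TTAGGGNNTTAGGG", minTract = 6))
})

test_that("tract calls equal the brute-force chain oracle on random sequences", {
    set.seed(101)
    for (rep in 1:12) {
        # random background with planted motif runs and inserts
        n <- sample(1000:5000, 1)
        s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
        for (k in seq_len(sample(1:4, 1))) {
            at <- sample(n - 400, 1)
            run <- strsplit(strrep(sample(c("TTAGGG", "CCCTAA"), 1),
                                   sample(10:50, 1)), "")[[1]]
            s[at:(at + length(run) - 1)] <- run
        }
        s <- paste(s, collapse = "")
        mg <- sample(c(12L, 24L, 48L), 1)
        mp <- sample(c(0.6, 0.8, 1), 1)
        mt <- sample(c(60L, 120L, 200L), 1)
        got <- tractsToDf(findRepeatTracts(s, minTract = mt, maxGap = mg,
                                           minPurity = mp))
        want <- oracleTracts(s, minTract = mt, maxGap = mg, minPurity = mp)
        expect_equal(got, want, ignore_attr = TRUE)
    }
})

test_that("tract detection mirrors under reverse complement", {
    set.seed(77)
    for (rep in 1:8) {
        n <- sample(500:3000, 1)
        s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
        at <- sample(n - 300, 1)
        s[at:(at + 239)] <- strsplit(strrep("TTAGGG", 40), "")[[1]]
        s <- paste(s, collapse = "")
        rc <- as.character(reverseComplement(DNAString(s)))
        fwd <- findRepeatTracts(s, minTract = 100)
        rev <- findRepeatTracts(rc, minTract = 100)
        expect_equal(length(fwd), length(rev))
        mapped <- data.frame(start = n - end(rev) + 1L,
                             end = n - start(rev) + 1L,
                             strand = ifelse(as.character(strand(rev)) == "+",
                                             "-", "+"),
                             unit_count = rev$unit_count,
                             purity = rev$purity)
        mapped <- mapped[order(mapped$start, mapped$strand), ]
        expect_equal(tractsToDf(fwd), mapped, ignore_attr = TRUE)
    }
})

test_that("returned tracts always satisfy span and purity bounds", {
    set.seed(13)
    for (rep in 1:6) {
        # degraded planted runs so candidates of varying purity exist
        clean <- strrep("TTAGGG", 60)
        noisy <- terraseq:::.corruptRead(clean, 0.08, 0, 0)
        bg <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE),
                    collapse = "")
        s <- paste0(bg, noisy, bg)
        tr <- findRepeatTracts(s, minTract = 30, maxGap = 30,
                               minPurity = 0.5)
        expect_gt(length(tr), 0L)
        expect_true(all(tr$purity >= 0.5 & tr$purity <= 1))
        expect_true(all(width(tr) >= 30))
        expect_true(all(tr$purity == 6 * tr$unit_count / width(tr)))
    }
})

test_that("tracts classify as terminal or interstitial by end distance", {
    gr <- GRanges("chr1", IRanges(c(6, 500001, 999001),
                                  c(3005, 500300, 999500)),
                  strand = "+", unit_count = 1L, purity = 1,
                  category = NA_character_)
    out <- classifyTracts(gr, c(chr1 = 1000000L), endWindow = 100000L)
    expect_equal(out$category,
                 c("terminal_p", "interstitial", "terminal_q"))
    expect_error(classifyTracts(gr, c(chr1 = 900000L)), "past")
    # only the closest tract to an end can be terminal
    two <- GRanges("chr1", IRanges(c(10, 5000), c(300, 5300)),
                   strand = "+", unit_count = 1L, purity = 1,
                   category = NA_character_)
    out2 <- classifyTracts(two, c(chr1 = 1000000L))
    expect_equal(out2$category, c("terminal_p", "interstitial"))
})

test_that("read tract measurement reports bulk length, tract span and 3' contact", {
    set.seed(9)
    uniq <- paste(sample(c("A", "C", "G"), 500, replace = TRUE),
                  collapse = "")
    r <- paste0(uniq, strrep("TTAGGG", 50))
    m <- measureReadTract(r)
    expect_equal(m$bulk_len, 800L)
    expect_equal(m$telo_len, 300L)
    expect_true(m$telo_touches_3prime)
    m2 <- measureReadTract(uniq)
    expect_equal(m2, list(bulk_len = 500L, telo_len = 0L,
                          telo_touches_3prime = FALSE))
    # tract in the middle of the read does not touch the 3' end
    m3 <- measureReadTract(paste0(uniq, strrep("TTAGGG", 50), uniq))
    expect_equal(m3$telo_len, 300L)
    expect_false(m3$telo_touches_3prime)
    expect_error(measureReadTract(""), "empty")
})

test_that("noisy-read tract length stays near a banded-alignment oracle", {
    set.seed(21)
    uniq <- paste(sample(c("A", "C", "G"), 400, replace = TRUE),
                  collapse = "")
    for (rep in 1:5) {
        clean <- paste0(uniq, strrep("TTAGGG", 100))
        noisy <- terraseq:::.corruptRead(clean, 0.05, 0.015, 0.015)
        got <- measureReadTract(noisy)$telo_len
        # oracle: best local alignment of a long telomeric reference
        # against the read bounds the recoverable tract span
        pa <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(strrep("TTAGGG", 110)),
            Biostrings::DNAString(noisy), type = "local",
            substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
                match = 1, mismatch = -1),
            gapOpening = 1, gapExtension = 1)
        oracleSpan <- Biostrings::width(Biostrings::subject(pa))
        expect_lt(abs(got - oracleSpan), 30)   # within a few motif units
    }
})

test_that("long-read alignment filtering keeps one unique record per read", {
    aln <- data.frame(
        read_id = c("a", "b", "b", "c", "d", "e", "e"),
        seq_id = "chr1",
        start = c(1, 10, 500, 20, 30, 40, 900),
        end = c(100, 110, 600, 120, 130, 140, 1000),
        mapq = c(0L, 60L, 60L, 60L, 60L, 30L, 50L),
        flag = c(0L, 0L, 2048L, 16L, 256L, 2048L, 2064L))
    out <- filterLongReadAlignments(aln)
    # a: mapq 0 dropped; b: primary kept, supplementary removed;
    # c: primary reverse kept; d: secondary dropped;
    # e: two supplementary, highest MAPQ kept
    expect_equal(sort(out$read_id), c("b", "c", "e"))
    expect_equal(out$start[out$read_id == "b"], 10)
    expect_equal(out$mapq[out$read_id == "e"], 50L)
    expect_equal(nrow(out), length(unique(out$read_id)))
    # idempotence
    expect_equal(filterLongReadAlignments(out), out)
    expect_equal(nrow(filterLongReadAlignments(aln[0, ])), 0L)
})

test_that("paired or duplicate flags are excluded from unique long reads", {
    aln <- data.frame(read_id = c("p", "q"), seq_id = "chr1",
                      start = c(1, 50), end = c(100, 150),
                      mapq = c(60L, 60L), flag = c(99L, 1024L))
    expect_equal(nrow(filterLongReadAlignments(aln)), 0L)
})
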