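test_that("read filtering applies the MAPQ and duplicate rules", {
    reads <- makeReads(pos = c(100, 200, 300, 400),
                       strand = c("W", "W", "C", "C"),
                       mapq = c(9L, 10L, 60L, 60L),
                       dup = c(FALSE, FALSE, TRUE, FALSE))
    out <- filterReads(reads, SCEParam())
    expect_equal(out$pos, c(200, 400))   # MAPQ 9 out, duplicate out
    expect_equal(nrow(filterReads(reads[0, ], SCEParam())), 0)
    bad <- makeReads(100, "X")
    expect_error(filterReads(bad, SCEParam()), "row")
})

test_that("isolated reads are flipped simultaneously, ends protected", {
    r1 <- makeReads(seq(100, 700, by = 100),
                    c("W", "W", "W", "C", "W", "W", "W"))
    out <- flipIsolatedReads(r1, SCEParam())
    expect_equal(out$nFlipped, 1)
    expect_true(all(out$reads$strand == "W"))

    r2 <- makeReads(seq(100, 600, by = 100),
                    c("W", "W", "C", "C", "W", "W"))
    out2 <- flipIsolatedReads(r2, SCEParam())
    expect_equal(out2$nFlipped, 0)
    expect_identical(out2$reads$strand, r2$strand)

    r3 <- makeReads(seq(100, 800, by = 100), rep("C", 8))
    out3 <- flipIsolatedReads(r3, SCEParam())
    expect_equal(out3$nFlipped, 0)

    # a lone opposite read at a chromosome end is never flipped
    r4 <- makeReads(seq(100, 700, by = 100),
                    c("C", "W", "W", "W", "W", "W", "W"))
    expect_equal(flipIsolatedReads(r4, SCEParam())$nFlipped, 0)
})

test_that("flip correction is idempotent on noise-free planted data", {
    g <- simulateGenome(1, 5e6, gapFraction = 0, seed = 71)
    sim <- simulateStrandSeqLibrary(g, nSCEs = 2, depth = 100,
                                    flipErrorRate = 0, dupRate = 0,
                                    mapqLowRate = 0, seed = 72)
    once <- flipIsolatedReads(sim$reads, SCEParam())
    twice <- flipIsolatedReads(once$reads, SCEParam())
    expect_identical(once$reads, twice$reads)
    expect_equal(twice$nFlipped, 0)
})

test_that("segmentation recovers clean two-state and one-state signals", {
    set.seed(81)
    r <- makeReads(sort(sample.int(1e6, 200)),
                   rep(c("C", "W"), each = 100))
    seg <- segmentDirectionality(r, SCEParam())
    expect_equal(nrow(seg), 2)
    expect_equal(seg$state, c("C", "W"))
    expect_equal(seg$lastIdx[1], 100)   # boundary between reads 100/101
    expect_equal(seg$nStateReads, c(100, 100))

    rW <- makeReads(sort(sample.int(1e6, 200)), rep("W", 200))
    segW <- segmentDirectionality(rW, SCEParam())
    expect_equal(nrow(segW), 1)
    expect_equal(segW$state, "W")

    expect_warning(
        segmentDirectionality(makeReads(c(1, 2), c("W", "C")),
                              SCEParam()),
        "single segment")
})

test_that("adjacent emitted segments always alternate in state", {
    for (s in 1:5) {
        g <- simulateGenome(1, 2e7, gapFraction = 0.05, seed = 90 + s)
        sim <- simulateStrandSeqLibrary(g, nSCEs = 3, depth = 150,
                                        flipErrorRate = 0.02,
                                        seed = 95 + s)
        fl <- flipIsolatedReads(filterReads(sim$reads, SCEParam()),
                                SCEParam())
        seg <- segmentDirectionality(fl$reads, SCEParam())
        if (nrow(seg) > 1)
            expect_true(all(seg$state[-1] != seg$state[-nrow(seg)]))
    }
})

test_that("planted single SCE is localized within the reported interval", {
    hits <- 0L
    for (i in 1:100) {
        g <- simulateGenome(1, 1e7, gapFraction = 0, seed = 100 + i)
        sim <- simulateStrandSeqLibrary(g, nSCEs = 1, depth = 20,
                                        flipErrorRate = 0.02,
                                        dupRate = 0, mapqLowRate = 0,
                                        seed = 300 + i)
        res <- callSCEsFromReads(sim$reads, SCEParam())
        ev <- evaluateSCECalls(res$events, sim$truth$breakpoints)
        if (!is.na(ev$recall) && ev$recall == 1) hits <- hits + 1L
    }
    expect_gte(hits, 95)
})

test_that("event calling enforces the three-read flank rule", {
    reads <- makeReads(
        pos = c(4999000, 4999400, 4999800, 5000200, 5000600, 5001000),
        strand = c("C", "C", "C", "W", "W", "W"))
    seg <- data.frame(chrom = "chr1",
                      firstReadPos = c(4999000, 5000200),
                      lastReadPos = c(4999800, 5001000),
                      state = c("C", "W"),
                      nStateReads = c(3L, 3L), nOtherReads = c(0L, 0L),
                      firstIdx = c(1L, 4L), lastIdx = c(3L, 6L))
    ev <- callSCEs(seg, reads, SCEParam())
    expect_length(ev, 1)
    # 0-based half-open interval between the boundary reads
    expect_equal(start(ev) - 1L, 4999800)
    expect_equal(end(ev), 5000200)
    expect_equal(ev$leftSupport, 3L)

    # left support 2 < 3: no event
    seg2 <- seg; seg2$nStateReads <- c(2L, 5L)
    expect_length(callSCEs(seg2, reads, SCEParam()), 0)

    # no strand-state change: no events
    segW <- data.frame(chrom = "chr1", firstReadPos = 1,
                       lastReadPos = 100, state = "W",
                       nStateReads = 10L, nOtherReads = 0L,
                       firstIdx = 1L, lastIdx = 10L)
    expect_length(callSCEs(segW, makeReads(1:10 * 10, rep("W", 10)),
                           SCEParam()), 0)
})

test_that("no emitted event ever has a flank below minSupport", {
    for (s in 1:5) {
        g <- simulateGenome(1, 2e7, gapFraction = 0.05, seed = 110 + s)
        sim <- simulateStrandSeqLibrary(g, nSCEs = 4, depth = 150,
                                        flipErrorRate = 0.02,
                                        seed = 120 + s)
        ev <- callSCEsFromReads(sim$reads, SCEParam())$events
        if (length(ev)) {
            expect_true(all(ev$leftSupport >= 3))
            expect_true(all(ev$rightSupport >= 3))
        }
    }
})

test_that("raising thresholds is monotone in reads kept and events called", {
    g <- simulateGenome(1, 2e7, gapFraction = 0, seed = 131)
    sim <- simulateStrandSeqLibrary(g, nSCEs = 3, depth = 150,
                                    flipErrorRate = 0.02,
                                    dupRate = 0.05, mapqLowRate = 0.2,
                                    seed = 132)
    nKept <- vapply(c(0, 10, 30, 61), function(q)
        nrow(filterReads(sim$reads, SCEParam(minMapq = q))),
        integer(1))
    expect_true(all(diff(nKept) <= 0))
    nEvents <- vapply(c(3, 10, 50, 200), function(ms)
        length(callSCEsFromReads(sim$reads,
                                 SCEParam(minSupport = ms))$events),
        integer(1))
    expect_true(all(diff(nEvents) <= 0))
})

test_that("clonal events are flagged strictly above the 25% rule", {
    mk <- function(libs, s, e) {
        gr <- GRanges("chr1", IRanges(rep(s, length(libs)),
                                      rep(e, length(libs))))
        gr$libraryId <- libs
        gr
    }
    # same interval in 6 of 20 libraries (30%): clonal
    ev <- c(mk(paste0("lib", 1:6), 1000, 2000),
            mk("lib7", 5000, 6000))
    out <- filterClonalEvents(ev, nLibraries = 20)
    expect_length(out$recurrent, 6)
    expect_length(out$nonRecurrent, 1)
    # 5 of 20 (exactly 25%): NOT clonal
    ev2 <- mk(paste0("lib", 1:5), 1000, 2000)
    out2 <- filterClonalEvents(ev2, nLibraries = 20)
    expect_length(out2$recurrent, 0)
    expect_length(out2$nonRecurrent, 5)
    # all unique: nothing flagged
    ev3 <- c(mk("a", 1, 10), mk("b", 100, 200), mk("c", 500, 900))
    expect_length(filterClonalEvents(ev3, 20)$recurrent, 0)
    expect_error(filterClonalEvents(ev, 0), "positive")
    # slop-based matching groups near-identical intervals
    ev4 <- c(mk(paste0("lib", 1:3), 1000, 2000),
             mk(paste0("lib", 4:6), 1005, 1995))
    out4 <- filterClonalEvents(ev4, nLibraries = 10, matchSlop = 10)
    expect_length(out4$recurrent, 6)
})
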