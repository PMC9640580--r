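test_that("gap masking is a bijection on non-gap bases", {
    # no gaps: identity
    m0 <- maskGaps(c(chr1 = 1e7), GRanges())
    expect_equal(mapToMasked(m0, c(0, 123, 9999999), chrom = "chr1"),
                 c(0, 123, 9999999))
    # one gap [4, 5) Mb: 6 Mb maps to 5 Mb
    m1 <- maskGaps(c(chr1 = 1e7),
                   GRanges("chr1", IRanges(4e6 + 1, 5e6)))
    expect_equal(mapToMasked(m1, 6e6, chrom = "chr1"), 5e6)
    expect_true(is.na(mapToMasked(m1, 4.5e6, chrom = "chr1")))
    expect_equal(unname(maskedLengths(m1)), 9e6)
    # round trip on random non-gap positions
    set.seed(42)
    pos <- sample(c(0:(4e6 - 1), 5e6:(1e7 - 1)), 1000)
    expect_equal(mapFromMasked(m1, mapToMasked(m1, pos, chrom = "chr1"),
                               chrom = "chr1"), pos)
})

test_that("circular shifts preserve counts, lengths and chromosomes", {
    msces <- list(chr1 = data.frame(start = c(1e6), end = c(1e6 + 100),
                                    id = "a"))
    L <- c(chr1 = 1e7)
    sh <- sceScope:::shiftMaskedSCEs(msces, 9.5e6, L)
    expect_equal(sh$chr1$start, 5e5)
    expect_equal(sh$chr1$end, 5e5 + 100)
    # n = 0 identity
    expect_equal(sceScope:::shiftMaskedSCEs(msces, 0, L), msces)
    # wrapping preserves the id and total length
    sh2 <- sceScope:::shiftMaskedSCEs(
        list(chr1 = data.frame(start = 9.99995e6, end = 1e7, id = "b")),
        1e4, L)
    expect_equal(sum(sh2$chr1$end - sh2$chr1$start), 50)
    expect_true(all(sh2$chr1$id == "b"))
    # per-chromosome counts invariant under arbitrary shifts
    set.seed(7)
    ms <- list(chr1 = data.frame(start = sort(runif(50, 0, 1e7 - 200)),
                                 end = NA, id = paste0("s", 1:50)))
    ms$chr1$end <- ms$chr1$start + 200
    for (n in c(0, 1234, 5e6, 9.9e6))
        expect_length(unique(
            sceScope:::shiftMaskedSCEs(ms, n, L)$chr1$id), 50)
})

test_that("overlap counting matches a per-base brute-force oracle", {
    expect_equal(countSCEOverlaps(
        GRanges("chr1", IRanges(101, 200)),
        GRanges("chr1", IRanges(151, 300))), 1)
    # half-open: abutting intervals do not overlap
    expect_equal(countSCEOverlaps(
        GRanges("chr1", IRanges(101, 200)),
        GRanges("chr1", IRanges(201, 300))), 0)
    set.seed(11)
    for (i in 1:50) {
        qs <- sample(0:9000, 100); qe <- qs + sample(1:500, 100,
                                                     replace = TRUE)
        ss <- sample(0:9000, 20); se <- ss + sample(1:800, 20,
                                                    replace = TRUE)
        fast <- countSCEOverlaps(
            GRanges("chr1", IRanges(qs + 1, qe)),
            GRanges("chr1", IRanges(ss + 1, se)))
        expect_equal(fast, oracleOverlapCount(qs, qe, ss, se, 10000))
    }
})

test_that("hotspot regions match per-base depth", {
    # two overlapping SCE intervals: one hotspot
    hs <- findHotspots(GRanges("chr1", IRanges(c(100, 150),
                                               c(200, 260))))
    expect_length(hs, 1)
    expect_equal(hs$nEvents, 2)
    # disjoint: none
    expect_length(findHotspots(
        GRanges("chr1", IRanges(c(100, 500), c(200, 600)))), 0)
    set.seed(13)
    for (i in 1:50) {
        s <- sample(0:5000, 30); e <- s + sample(10:400, 30,
                                                 replace = TRUE)
        depth <- oracleDepth(s, e, 6000)
        hs <- findHotspots(GRanges("chr1", IRanges(s + 1, e)),
                           minEvents = 2)
        oracleBases <- which(depth >= 2)
        fastBases <- unlist(lapply(seq_along(hs), function(j)
            start(hs)[j]:end(hs)[j]))
        expect_equal(sort(fastBases), oracleBases)
        if (length(hs))
            expect_equal(max(hs$maxDepth), max(depth))
    }
})

test_that("hotspot binomial tail equals direct summation and Monte Carlo", {
    expect_equal(hotspotPvalue(0, 10, 1e6, 1e8), 1)
    expect_equal(hotspotPvalue(2, 10, 1e6, 1e8),
                 oracleBinomTail(2, 10, 0.01), tolerance = 1e-12)
    expect_equal(hotspotPvalue(2, 10, 1e6, 1e8), 0.004266,
                 tolerance = 1e-4)
    set.seed(17)
    for (case in list(c(2, 10, 100), c(3, 20, 50), c(2, 15, 200))) {
        k <- case[1]; N <- case[2]; nb <- case[3]
        reps <- 1e5
        binHits <- matrix(sample.int(nb, N * reps, replace = TRUE),
                          nrow = reps)
        mc <- mean(rowSums(binHits == 1L) >= k)
        p <- hotspotPvalue(k, N, 1, nb)
        expect_lt(abs(mc - p), 3 * sqrt(p * (1 - p) / reps))
    }
    expect_error(hotspotPvalue(2, 10, 0, 100), "positive")
    # Bonferroni option scales by the number of bins, capped at 1
    expect_equal(hotspotPvalue(2, 10, 1e6, 1e8, bonferroni = TRUE),
                 min(1, 100 * hotspotPvalue(2, 10, 1e6, 1e8)))
})

test_that("G4 scanning matches the pattern and an exhaustive oracle", {
    # loops of length 1, x = 3: a single motif spanning the string
    m <- scanG4("GGGAGGGTGGGCGGG", loopMax = 3, bothStrands = FALSE)
    expect_equal(nrow(m), 1)
    expect_equal(c(m$start, m$end), c(0, 15))
    # first loop of length 5 requires x = 7
    expect_equal(nrow(scanG4("GGGAAAAAGGGAGGGAGGG", loopMax = 3,
                             bothStrands = FALSE)), 0)
    expect_equal(nrow(scanG4("GGGAAAAAGGGAGGGAGGG", loopMax = 7,
                             bothStrands = FALSE)), 1)
    # reverse-strand motif found only when both strands are scanned
    cseq <- "CCCACCCTCCCACCC"
    expect_equal(nrow(scanG4(cseq, loopMax = 3, bothStrands = FALSE)), 0)
    both <- scanG4(cseq, loopMax = 3)
    expect_equal(nrow(both), 1)
    expect_equal(both$strand, "-")
    expect_error(scanG4("GGGAXGGG", loopMax = 3), "non-nucleotide")

    set.seed(19)
    for (i in 1:50) {
        s <- randomGRichSeq(1500)
        counts <- vapply(c(3, 7, 12), function(x) {
            got <- nrow(scanG4(s, loopMax = x, bothStrands = FALSE))
            expect_equal(got, oracleG4Count(s, loopMax = x))
            got
        }, integer(1))
        expect_true(all(diff(counts) >= 0))   # monotone in x
    }
})

test_that("permutation test handles degenerate geometries correctly", {
    g <- simulateGenome(1, 1e7, gapFraction = 0, seed = 61)
    # track covering the whole chromosome: shifts cannot change overlap
    whole <- GRanges("chr1", IRanges(1, 1e7))
    sces <- plantEnrichedSCEs(g, whole, 20, 1, seed = 62)
    res <- runPermutationTest(sces, whole, g,
                              PermParam(nPerm = 200), seed = 63)
    expect_true(all(permutedOverlaps(res) == observedOverlap(res)))
    expect_equal(enrichment(res), 1)
    expect_equal(pEnrich(res), 1)
    expect_equal(pDeplete(res), 1)
    # empty SCE set: degenerate flag
    resE <- runPermutationTest(GRanges(), whole, g,
                               PermParam(nPerm = 100), seed = 1)
    expect_true(resE@degenerate)
    expect_equal(observedOverlap(resE), 0L)
    # enrichment equals 1 whenever observed equals the permuted median
    expect_equal(observedOverlap(res) /
                 stats::median(permutedOverlaps(res)), 1)
})

test_that("size cutoff removes unlocalized SCE intervals before testing", {
    g <- simulateGenome(1, 1e7, gapFraction = 0, seed = 71)
    tr <- simulateFeatureTrack(g, 10, 1e5, seed = 72)
    wide <- GRanges("chr1", IRanges(1, 2e5))        # 200 kb interval
    narrow <- GRanges("chr1", IRanges(5e6, 5e6 + 50))
    res <- runPermutationTest(c(wide, narrow), tr, g,
                              PermParam(nPerm = 50, sizeCutoff = 1e5),
                              seed = 73)
    expect_equal(res@nSCE, 1L)
})

test_that("strong planted enrichment is reported below the p floor", {
    g <- simulateGenome(1, 1e8, gapFraction = 0.05, seed = 81)
    tr <- simulateFeatureTrack(g, 50, 1e5, seed = 82)
    sces <- plantEnrichedSCEs(g, tr, 100, 0.5, seed = 83)
    res <- runPermutationTest(sces, tr, g, PermParam(nPerm = 1000),
                              seed = 84)
    expect_lt(pEnrich(res), 1 / 1000)
    expect_equal(res@direction, "enriched")
    expect_gt(enrichment(res), 5)
    rep <- permReport(list(res))
    expect_equal(rep$pEnrichLabel, "< 0.001")
})
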