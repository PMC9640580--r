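test_that("simulateGenome honors size, gap fraction and determinism", {
    g0 <- simulateGenome(1, 1e7, gapFraction = 0, seed = 7)
    expect_equal(unname(chromSizes(g0)), 1e7)
    expect_length(gapRanges(g0), 0)

    g1 <- simulateGenome(1, 1e7, gapFraction = 0.1, seed = 7,
                         withSequence = TRUE)
    gapBp <- sum(width(gapRanges(g1)))
    expect_gte(gapBp, 0.8e6)
    expect_lte(gapBp, 1.2e6)
    # gap bases are N, non-gap bases are ACGT
    s <- as.character(genomeSequence(g1)[["chr1"]])
    gp <- gapRanges(g1)
    expect_true(all(strsplit(substr(s, start(gp)[1], end(gp)[1]),
                             NULL)[[1]] == "N"))

    g2 <- simulateGenome(1, 1e7, gapFraction = 0.1, seed = 7,
                         withSequence = TRUE)
    expect_identical(as.character(genomeSequence(g1)),
                     as.character(genomeSequence(g2)))
    expect_identical(as.data.frame(gapRanges(g1)),
                     as.data.frame(gapRanges(g2)))

    expect_error(simulateGenome(1, -5), "positive")
})

test_that("genome FASTA round-trips byte-identically", {
    g <- simulateGenome(1, 1e5, gapFraction = 0.05, seed = 3,
                        withSequence = TRUE)
    d1 <- file.path(tempdir(), "g1"); d2 <- file.path(tempdir(), "g2")
    writeGenome(g, d1)
    writeGenome(simulateGenome(1, 1e5, gapFraction = 0.05, seed = 3,
                               withSequence = TRUE), d2)
    expect_identical(unname(tools::md5sum(file.path(d1, "genome.fa"))),
                     unname(tools::md5sum(file.path(d2, "genome.fa"))))
})

test_that("strand-seq simulation: conservation and planted structure", {
    g <- simulateGenome(1, 1e7, gapFraction = 0.1, seed = 5)
    sim <- simulateStrandSeqLibrary(g, nSCEs = 0, depth = 100,
                                    flipErrorRate = 0, dupRate = 0,
                                    mapqLowRate = 0, seed = 8)
    # read count = depth x non-gap Mb within rounding
    expect_equal(nrow(sim$reads), round(100 * 9e6 / 1e6))
    # no planted switch, no noise: one strand everywhere
    expect_length(unique(sim$reads$strand), 1)
    # no reads inside gaps
    rgr <- GRanges(sim$reads$chrom,
                   IRanges(sim$reads$pos + 1, sim$reads$pos + 1))
    expect_equal(sum(countOverlaps(rgr, gapRanges(g))), 0)

    sim1 <- simulateStrandSeqLibrary(g, nSCEs = 1, depth = 100,
                                     flipErrorRate = 0, dupRate = 0,
                                     mapqLowRate = 0, seed = 9)
    bp <- sim1$truth$breakpoints$pos[1]
    left <- sim1$reads$strand[sim1$reads$pos < bp]
    right <- sim1$reads$strand[sim1$reads$pos >= bp]
    expect_length(unique(left), 1)
    expect_length(unique(right), 1)
    expect_false(unique(left) == unique(right))
})

test_that("noise rates are calibrated within 3 binomial SEs", {
    g <- simulateGenome(1, 2e7, gapFraction = 0, seed = 21)
    sim <- simulateStrandSeqLibrary(g, nSCEs = 2, depth = 150,
                                    flipErrorRate = 0.02,
                                    dupRate = 0.05,
                                    mapqLowRate = 0.05, seed = 22)
    n <- nrow(sim$reads)
    expect_gte(n, 1000)
    flipped <- mean(sim$reads$strand != sim$truth$trueStrand)
    se <- sqrt(0.02 * 0.98 / n)
    expect_lt(abs(flipped - 0.02), 3 * se)
    se <- sqrt(0.05 * 0.95 / n)
    expect_lt(abs(mean(sim$reads$dup) - 0.05), 3 * se)
    expect_lt(abs(mean(sim$reads$mapq < 10) - 0.05), 3 * se)
})

test_that("breakpoints that cannot be separated are rejected", {
    g <- simulateGenome(1, 1e5, gapFraction = 0, seed = 2)
    # 50 breakpoints each needing 2e6/10 = 200 kb spacing on 100 kb
    expect_error(
        simulateStrandSeqLibrary(g, nSCEs = 50, depth = 10, seed = 3),
        "separate")
})

test_that("feature tracks avoid gaps and report coverage", {
    g <- simulateGenome(1, 1e8, gapFraction = 0.05, seed = 31)
    empty <- simulateFeatureTrack(g, 0, 1e5, seed = 1)
    expect_length(empty, 0)

    tr <- simulateFeatureTrack(g, 10, 1e5, seed = 32)
    expect_length(tr, 10)
    expect_equal(S4Vectors::metadata(tr)$coveredFraction, 0.01)
    expect_equal(sum(countOverlaps(tr, gapRanges(g))), 0)
    expect_true(all(width(GenomicRanges::reduce(tr)) >= 1e5))

    expect_error(simulateFeatureTrack(g, 2000, 1e5, seed = 1),
                 "exceeds non-gap space")
})

test_that("plantEnrichedSCEs places the requested fractions", {
    g <- simulateGenome(1, 1e8, gapFraction = 0.05, seed = 41)
    tr <- simulateFeatureTrack(g, 20, 1e5, seed = 42)
    allIn <- plantEnrichedSCEs(g, tr, 40, 1, seed = 43)
    expect_equal(sum(countOverlaps(allIn, tr) > 0), 40)
    noneIn <- plantEnrichedSCEs(g, tr, 40, 0, seed = 44)
    expect_equal(sum(countOverlaps(noneIn, tr) > 0), 0)
    half <- plantEnrichedSCEs(g, tr, 101, 0.5, seed = 45)
    expect_equal(sum(half$inside), round(101 * 0.5))
    expect_error(plantEnrichedSCEs(g, GRanges(), 10, 0.5, seed = 1),
                 "empty")
})

test_that("deletion cohorts: group parameters shape the planted truth", {
    g <- simulateGenome(1, 2e7, gapFraction = 0, seed = 51)
    cfs <- simulateFeatureTrack(g, 8, 5e5, name = "CFS", seed = 52)
    co <- simulateDeletionCohort(
        g, cfs, nSamplesPerGroup = c(HRD = 10, HRP = 10),
        delsPerSample = 100, cfsFractionByGroup = c(HRD = 1, HRP = 1),
        mhGeometricPByGroup = c(HRD = 0.4, HRP = 0.8),
        lengthRange = c(1e3, 1e4), plantSequence = FALSE, seed = 53)
    d <- co$deletions
    # cfsFraction = 1: every deletion fully inside a CFS interval
    expect_true(all(deletionInCFS(d, cfs)))
    # geometric p 0.4 (HRD) vs 0.8 (HRP): HRD mean planted MH larger
    expect_gt(mean(d$mhLength[d$group == "HRD"]),
              mean(d$mhLength[d$group == "HRP"]))
    # determinism
    co2 <- simulateDeletionCohort(
        g, cfs, nSamplesPerGroup = c(HRD = 10, HRP = 10),
        delsPerSample = 100, cfsFractionByGroup = c(HRD = 1, HRP = 1),
        mhGeometricPByGroup = c(HRD = 0.4, HRP = 0.8),
        lengthRange = c(1e3, 1e4), plantSequence = FALSE, seed = 53)
    expect_identical(d, co2$deletions)
    expect_error(
        simulateDeletionCohort(g, cfs,
                               nSamplesPerGroup = c(HRD = 2, HRP = 2),
                               delsPerSample = 2,
                               lengthRange = c(3e7, 4e7),
                               plantSequence = FALSE, seed = 1),
        "exceeds chromosome")
})

test_that("planted junction microhomology is recovered by an oracle", {
    g <- simulateGenome(1, 5e6, gapFraction = 0, seed = 61,
                        withSequence = TRUE)
    cfs <- simulateFeatureTrack(g, 4, 3e5, name = "CFS", seed = 62)
    co <- simulateDeletionCohort(
        g, cfs, nSamplesPerGroup = c(HRD = 3, HRP = 3),
        delsPerSample = 25, lengthRange = c(200, 2000), seed = 63)
    seqChars <- strsplit(
        as.character(genomeSequence(co$genome)[["chr1"]]), NULL)[[1]]
    d <- co$deletions
    rec <- vapply(seq_len(nrow(d)), function(i)
        oracleMH(seqChars, d$start[i], d$end[i]), double(1))
    expect_true(all(rec >= d$mhLength))
    expect_equal(mean(rec == d$mhLength), 1)
})
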