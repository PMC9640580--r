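#' Simulate a reference genome with assembly gaps
#'
#' Generates a `SyntheticGenome`: chromosome lengths, non-overlapping
#' assembly-gap intervals occupying approximately `gapFraction` of each
#' chromosome, and optionally a random nucleotide sequence in which gap
#' bases are `N`.
#'
#' Gap placement: the target total gap length per chromosome is
#' `round(gapFraction * size)`, split over a small number of gap intervals
#' (mean length ~500 kb) whose positions are drawn uniformly subject to
#' non-overlap, so realized gap content is exact per chromosome.
#'
#' @param nChrom Number of chromosomes.
#' @param sizes Chromosome lengths in bp (recycled to `nChrom`).
#' @param gapFraction Fraction of each chromosome covered by assembly gaps;
#'   must lie in `[0, 0.5)`.
#' @param seed Integer seed; identical seeds give identical genomes.
#' @param withSequence Simulate a uniform-random A/C/G/T sequence (gaps are
#'   written as `N`)? Default `FALSE`.
#' @param chromNames Optional chromosome names (default `"chr1"`, ...).
#'
#' @return A [SyntheticGenome-class] object.
#' @examples
#' g <- simulateGenome(1, 10e6, gapFraction = 0.05, seed = 1)
#' chromSizes(g)
#' @export
simulateGenome <- function(nChrom = 1L, sizes = 1e8, gapFraction = 0.05,
                           seed = NULL, withSequence = FALSE,
                           chromNames = NULL) {
    if (any(!is.finite(sizes)) || any(sizes <= 0))
        stop("chromosome sizes must be positive")
    checkProportion(gapFraction, "gapFraction")
    if (gapFraction >= 0.5) stop("gapFraction must be < 0.5")
    sizes <- as.numeric(rep_len(sizes, nChrom))
    if (is.null(chromNames)) chromNames <- paste0("chr", seq_len(nChrom))

    withSeed(seed, {
        gapList <- vector("list", nChrom)
        for (i in seq_len(nChrom)) {
            gapList[[i]] <- placeGaps(sizes[i], gapFraction)
        }
        gaps <- do.call(rbind, lapply(seq_len(nChrom), function(i) {
            g <- gapList[[i]]
            if (nrow(g) == 0L) return(NULL)
            cbind(chromIdx = i, g)
        }))
        if (is.null(gaps)) {
            gapGR <- GRanges(seqinfo = Seqinfo(chromNames, sizes))
        } else {
            gapGR <- GRanges(chromNames[gaps[, "chromIdx"]],
                             IRanges(start = gaps[, "start"] + 1,
                                     end = gaps[, "end"]))
        }
        seqence <- NULL
        if (withSequence) {
            bases <- charToRaw("ACGT")
            seqs <- vapply(seq_len(nChrom), function(i) {
                s <- bases[sample.int(4L, sizes[i], replace = TRUE)]
                g <- gapList[[i]]
                if (nrow(g) > 0L) {
                    nRaw <- charToRaw("N")
                    for (j in seq_len(nrow(g)))
                        s[(g[j, "start"] + 1):g[j, "end"]] <- nRaw
                }
                rawToChar(s)
            }, character(1))
            seqence <- DNAStringSet(seqs)
            names(seqence) <- chromNames
        }
        si <- Seqinfo(chromNames, sizes)
        GenomeInfoDb::seqlevels(gapGR) <- chromNames
        GenomeInfoDb::seqinfo(gapGR) <- si
        new("SyntheticGenome", seqinfo = si, gaps = sort(gapGR),
            sequence = seqence,
            seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
    })
}

# Place non-overlapping gaps totalling round(fraction * size) bp on
# [0, size); returns a matrix with 0-based half-open start/end columns.
placeGaps <- function(size, fraction) {
    total <- round(fraction * size)
    if (total < 1)
        return(matrix(numeric(0), ncol = 2,
                      dimnames = list(NULL, c("start", "end"))))
    k <- max(1L, round(total / 5e5))
    # random split of the total into k positive lengths
    if (k > 1L) {
        cuts <- sort(sample.int(total - 1L, k - 1L))
        lens <- diff(c(0, cuts, total))
    } else {
        lens <- total
    }
    free <- size - total
    if (free < k + 1)
        stop("not enough non-gap space to place gaps")
    # spacings >= 1 between and around gaps
    inner <- free - (k + 1)
    u <- sort(stats::runif(k, 0, inner))
    spac <- diff(c(0, u, inner)) + 1
    starts <- cumsum(spac[seq_len(k)]) + c(0, cumsum(lens))[seq_len(k)]
    starts <- floor(starts)
    cbind(start = starts, end = starts + lens)
}

#' Simulate a feature track outside assembly gaps
#'
#' Places `nFeatures` non-overlapping intervals of length `meanLength`
#' uniformly on the genome, rejecting placements that intersect an
#' assembly gap or a previously placed feature.
#'
#' @param genome A [SyntheticGenome-class].
#' @param nFeatures Number of intervals to place.
#' @param meanLength Interval length in bp.
#' @param name Track label stored in `metadata(track)$name`.
#' @param seed Integer seed.
#'
#' @return A sorted [GenomicRanges::GRanges] of non-overlapping intervals,
#'   none intersecting a gap; `metadata()$coveredFraction` records the
#'   fraction of the genome covered.
#' @export
simulateFeatureTrack <- function(genome, nFeatures, meanLength,
                                 name = "custom", seed = NULL) {
    stopifnot(is(genome, "SyntheticGenome"))
    sl <- chromSizes(genome)
    gapBp <- sum(as.numeric(width(gapRanges(genome))))
    nonGap <- sum(as.numeric(sl)) - gapBp
    if (nFeatures * meanLength > nonGap)
        stop("requested feature coverage exceeds non-gap space")
    if (nFeatures == 0L) {
        out <- GRanges(seqinfo = genome@seqinfo)
        S4Vectors::metadata(out) <- list(name = name, coveredFraction = 0)
        return(out)
    }
    withSeed(seed, {
        placed <- GRanges(seqinfo = genome@seqinfo)
        avoid <- gapRanges(genome)
        tries <- 0L
        maxTries <- 1000L * nFeatures
        while (length(placed) < nFeatures) {
            if ((tries <- tries + 1L) > maxTries)
                stop("could not place features outside gaps; ",
                     "reduce nFeatures or meanLength")
            ci <- sample.int(length(sl), 1L, prob = as.numeric(sl))
            if (sl[ci] <= meanLength) next
            s0 <- floor(stats::runif(1, 0, sl[ci] - meanLength))
            cand <- GRanges(names(sl)[ci],
                            IRanges(s0 + 1, s0 + meanLength))
            GenomeInfoDb::seqlevels(cand) <- seqlevels(genome@seqinfo)
            if (!length(findOverlaps(cand, avoid)) &&
                !length(findOverlaps(cand, placed)))
                placed <- c(placed, cand)
        }
        out <- sort(placed)
        S4Vectors::metadata(out) <- list(
            name = name,
            coveredFraction = sum(as.numeric(width(out))) /
                sum(as.numeric(sl)))
        out
    })
}
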