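#' Simulate a haploid Strand-seq library with planted SCEs
#'
#' Generates a per-cell aligned-read table for a haploid genome. Template
#' strand starts Watson (`W`) at the left end of each chromosome and
#' alternates at every planted sister-chromatid-exchange breakpoint. Each
#' read reports its template strand, except that with probability
#' `flipErrorRate` the label is inverted (sequencing/mapping noise); a
#' fraction `dupRate` of reads is flagged duplicate, and a fraction
#' `mapqLowRate` is drawn with MAPQ below 10. Reads are placed uniformly
#' on non-gap space; the read count per chromosome is
#' `round(depth * nonGapMb)`.
#'
#' @param genome A [SyntheticGenome-class].
#' @param nSCEs Number of SCE breakpoints to plant (distributed over
#'   chromosomes proportionally to non-gap length).
#' @param depth Reads per non-gap megabase (typical Strand-seq libraries
#'   run at roughly 100-300 reads/Mb; default 200).
#' @param flipErrorRate Probability a read's reported strand is inverted;
#'   must be `< 0.5`.
#' @param dupRate Fraction of reads flagged as PCR/optical duplicates.
#' @param mapqLowRate Fraction of reads with MAPQ below 10 (drawn
#'   uniformly from 0-9; remaining reads draw MAPQ 10-60).
#' @param seed Integer seed.
#' @param libraryId Library label carried into downstream SCE calls.
#'
#' @return A list with elements
#'   \describe{
#'     \item{reads}{data.frame with columns `chrom`, `pos` (0-based),
#'       `strand` (`W`/`C`), `mapq`, `dup` - sorted by chromosome and
#'       position.}
#'     \item{truth}{list: `breakpoints` (data.frame `chrom`, `pos`),
#'       `trueStrand` (per-read template strand aligned with `reads`),
#'       the noise parameters and the seed.}
#'   }
#' @export
simulateStrandSeqLibrary <- function(genome, nSCEs = 5L, depth = 200,
                                     flipErrorRate = 0.02,
                                     dupRate = 0.05, mapqLowRate = 0.05,
                                     seed = NULL, libraryId = "lib1") {
    stopifnot(is(genome, "SyntheticGenome"), nSCEs >= 0L)
    checkProportion(flipErrorRate, "flipErrorRate")
    if (flipErrorRate >= 0.5) stop("flipErrorRate must be < 0.5")
    checkProportion(dupRate, "dupRate")
    checkProportion(mapqLowRate, "mapqLowRate")
    mask <- maskGaps(genome)
    mlen <- maskedLengths(mask)
    minSep <- 2e6 / depth   # two mean read spacings

    withSeed(seed, {
        # distribute SCEs over chromosomes by non-gap length
        chromOf <- if (nSCEs > 0L)
            sample(names(mlen), nSCEs, replace = TRUE,
                   prob = mlen / sum(mlen)) else character(0)
        bpList <- list()
        readList <- list()
        for (chrom in names(mlen)) {
            L <- mlen[[chrom]]
            nb <- sum(chromOf == chrom)
            if (nb * minSep * 2 > L)
                stop("cannot separate ", nb, " breakpoints by ",
                     "2/depth spacing on ", chrom)
            # rejection-sample breakpoints with pairwise separation
            bp <- numeric(0)
            tries <- 0L
            while (length(bp) < nb) {
                if ((tries <- tries + 1L) > 1000L * max(nb, 1L))
                    stop("cannot separate breakpoints by 2/depth ",
                         "spacing on ", chrom)
                cand <- floor(stats::runif(1, minSep, L - minSep))
                if (!length(bp) || all(abs(bp - cand) >= minSep))
                    bp <- c(bp, cand)
            }
            bp <- sort(bp)
            nReads <- round(depth * L / 1e6)
            mpos <- floor(stats::runif(nReads, 0, L))
            # template state: W for an even number of breakpoints at or
            # before the read position, C otherwise
            nLeft <- findInterval(mpos, bp)
            template <- ifelse(nLeft %% 2L == 0L, "W", "C")
            refPos <- mapFromMasked(mask, mpos, chrom)
            o <- order(refPos)
            readList[[chrom]] <- data.frame(
                chrom = chrom, pos = refPos[o],
                template = template[o], stringsAsFactors = FALSE)
            if (nb > 0L)
                bpList[[chrom]] <- data.frame(
                    chrom = chrom,
                    pos = mapFromMasked(mask, bp, chrom))
        }
        reads <- do.call(rbind, readList)
        rownames(reads) <- NULL
        n <- nrow(reads)
        flip <- stats::runif(n) < flipErrorRate
        strand <- reads$template
        strand[flip] <- ifelse(strand[flip] == "W", "C", "W")
        mapqLow <- stats::runif(n) < mapqLowRate
        mapq <- integer(n)
        mapq[mapqLow] <- sample(0:9, sum(mapqLow), replace = TRUE)
        mapq[!mapqLow] <- sample(10:60, sum(!mapqLow), replace = TRUE)
        dup <- stats::runif(n) < dupRate
        out <- data.frame(chrom = reads$chrom, pos = reads$pos,
                          strand = strand, mapq = mapq, dup = dup,
                          stringsAsFactors = FALSE)
        breakpoints <- if (length(bpList)) do.call(rbind, bpList) else
            data.frame(chrom = character(0), pos = numeric(0))
        rownames(breakpoints) <- NULL
        list(reads = out,
             truth = list(breakpoints = breakpoints,
                          trueStrand = reads$template,
                          libraryId = libraryId,
                          flipErrorRate = flipErrorRate,
                          dupRate = dupRate,
                          mapqLowRate = mapqLowRate,
                          depth = depth,
                          seed = if (is.null(seed)) NA_integer_
                                 else as.integer(seed)))
    })
}

#' Plant SCE midpoints with controlled feature enrichment
#'
#' Places `round(nSCEs * insideFraction)` SCE midpoints uniformly inside
#' the intervals of a feature track and the remainder uniformly on
#' non-gap, non-track space, emulating a known degree of enrichment of
#' SCEs at a genomic feature.
#'
#' @param genome A [SyntheticGenome-class].
#' @param track Feature track ([GenomicRanges::GRanges]).
#' @param nSCEs Total number of SCE points.
#' @param insideFraction Fraction of SCEs planted inside the track, in
#'   `[0, 1]`.
#' @param width Width (bp) of the reported SCE uncertainty interval,
#'   centred on the planted midpoint (default 1, a point).
#' @param seed Integer seed.
#'
#' @return A [GenomicRanges::GRanges] of SCE intervals with a logical
#'   metadata column `inside` (the planted ground truth).
#' @export
plantEnrichedSCEs <- function(genome, track, nSCEs, insideFraction,
                              width = 1L, seed = NULL) {
    stopifnot(is(genome, "SyntheticGenome"))
    checkProportion(insideFraction, "insideFraction", maxOpen = FALSE)
    if (insideFraction > 0 && length(track) == 0L)
        stop("track is empty but insideFraction > 0")
    nIn <- round(nSCEs * insideFraction)
    nOut <- nSCEs - nIn
    sl <- chromSizes(genome)
    withSeed(seed, {
        mids <- character(0); pos <- numeric(0); inside <- logical(0)
        if (nIn > 0L) {
            w <- as.numeric(width(track))
            idx <- sample.int(length(track), nIn, replace = TRUE,
                              prob = w)
            p <- floor(start(track)[idx] - 1 +
                       stats::runif(nIn) * w[idx])
            mids <- c(mids, as.character(seqnames(track))[idx])
            pos <- c(pos, p)
            inside <- c(inside, rep(TRUE, nIn))
        }
        if (nOut > 0L) {
            avoid <- reduce(c(granges(gapRanges(genome)),
                              granges(track)), min.gapwidth = 0L)
            got <- 0L; tries <- 0L
            while (got < nOut) {
                if ((tries <- tries + 1L) > 1000L)
                    stop("could not place SCEs outside track and gaps")
                nDraw <- 2L * (nOut - got)
                ci <- sample.int(length(sl), nDraw, replace = TRUE,
                                 prob = as.numeric(sl))
                p <- floor(stats::runif(nDraw) * sl[ci])
                cand <- GRanges(names(sl)[ci], IRanges(p + 1, p + 1))
                ok <- which(countOverlaps(cand, avoid) == 0L)
                ok <- utils::head(ok, nOut - got)
                mids <- c(mids, names(sl)[ci[ok]])
                pos <- c(pos, p[ok])
                inside <- c(inside, rep(FALSE, length(ok)))
                got <- got + length(ok)
            }
        }
        half <- floor((width - 1) / 2)
        s0 <- pmax(0, pos - half)
        gr <- GRanges(mids, IRanges(start = s0 + 1,
                                    end = pmin(s0 + width,
                                               sl[mids])))
        GenomeInfoDb::seqlevels(gr) <- names(sl)
        GenomeInfoDb::seqinfo(gr) <- genome@seqinfo
        gr$inside <- inside
        gr$midpoint <- pos
        sort(gr)
    })
}
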