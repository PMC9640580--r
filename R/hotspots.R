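#' Find SCE hotspots by interval stacking
#'
#' Identifies maximal genomic regions where at least `minEvents` SCE
#' uncertainty intervals (pooled over libraries) overlap the same bases -
#' the interval-intersection depth reaches `minEvents`.
#'
#' @param sces [GenomicRanges::GRanges] of SCE intervals.
#' @param minEvents Minimum stacking depth (default 2).
#' @return A [GenomicRanges::GRanges] of candidate hotspot regions with
#'   metadata columns `nEvents` (number of SCE intervals overlapping the
#'   region), `maxDepth`, and `width`.
#' @export
findHotspots <- function(sces, minEvents = 2L) {
    if (!length(sces)) {
        out <- GRanges()
        out$nEvents <- integer(0); out$maxDepth <- integer(0)
        return(out)
    }
    cov <- coverage(sces)
    hs <- GRanges(slice(cov, lower = minEvents, rangesOnly = TRUE))
    if (length(hs)) {
        hs$nEvents <- countOverlaps(hs, sces, ignore.strand = TRUE)
        views <- slice(cov, lower = minEvents)
        hs$maxDepth <- unlist(lapply(views, function(v)
            as.integer(max(v))), use.names = FALSE)
    } else {
        hs$nEvents <- integer(0); hs$maxDepth <- integer(0)
    }
    hs
}

#' Binomial tail probability for an SCE hotspot
#'
#' The genome is conceptually divided into bins of the hotspot's size;
#' given `NTotal` SCEs detected in the library/cell line, the number
#' falling in one particular bin is Binomial(`NTotal`,
#' `binSize / genomeSize`). Returns the upper tail `P(X >= k)` - the
#' chance of finding at least the observed number of SCEs in one bin.
#'
#' @param k Observed SCE count in the bin.
#' @param NTotal Total SCEs detected.
#' @param binSize Hotspot (bin) width in bp.
#' @param genomeSize Genome size (non-gap bp) used for the bin fraction.
#' @param bonferroni Multiply by the number of bins
#'   (`floor(genomeSize / binSize)`), capped at 1? Default `FALSE`.
#' @return Probability (vectorized over `k`).
#' @examples
#' hotspotPvalue(2, 10, 1e6, 1e8)  # ~0.004266
#' @export
hotspotPvalue <- function(k, NTotal, binSize, genomeSize,
                          bonferroni = FALSE) {
    if (any(binSize <= 0)) stop("binSize must be positive")
    if (any(binSize > genomeSize))
        stop("binSize must not exceed genomeSize")
    if (any(k > NTotal)) stop("k must not exceed NTotal")
    p <- stats::pbinom(k - 1, NTotal, binSize / genomeSize,
                       lower.tail = FALSE)
    if (bonferroni)
        p <- pmin(1, p * floor(genomeSize / binSize))
    p
}
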