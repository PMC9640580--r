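#' Build a gap-masked coordinate space
#'
#' Constructs the bijection between non-gap reference bases and a
#' concatenated per-chromosome "masked" space in which assembly gaps are
#' removed and the remaining segments juxtaposed, preserving order.
#' Circular shifts performed in masked space can therefore never place an
#' interval inside a gap, which is the purpose of excluding annotated
#' assembly gaps before permutation.
#'
#' @param genome A [SyntheticGenome-class], or a named vector of
#'   chromosome lengths.
#' @param gaps Gap intervals as a [GenomicRanges::GRanges] (ignored when
#'   `genome` is a `SyntheticGenome`).
#'
#' @return A [GapMask-class] object.
#' @examples
#' g <- simulateGenome(1, 10e6, gapFraction = 0.1, seed = 1)
#' m <- maskGaps(g)
#' mapToMasked(m, "chr1", 6e6)
#' @export
maskGaps <- function(genome, gaps = NULL) {
    if (is(genome, "SyntheticGenome")) {
        sl <- chromSizes(genome)
        gaps <- gapRanges(genome)
    } else {
        sl <- genome
        if (is.null(names(sl))) stop("chromosome sizes must be named")
        if (is.null(gaps)) gaps <- GRanges()
    }
    red <- reduce(gaps, min.gapwidth = 0L)
    if (sum(width(red)) != sum(width(gaps)))
        stop("gaps must be non-overlapping")
    segStart <- segEnd <- segOffset <- list()
    maskedLength <- numeric(0)
    for (chrom in names(sl)) {
        g <- gaps[as.character(seqnames(gaps)) == chrom]
        g <- sort(g)
        # 0-based half-open non-gap segments
        gs <- start(g) - 1
        ge <- end(g)
        bnd <- c(0, as.vector(rbind(gs, ge)), sl[[chrom]])
        ss <- bnd[seq(1, length(bnd), by = 2)]
        se <- bnd[seq(2, length(bnd), by = 2)]
        keep <- se > ss
        ss <- ss[keep]; se <- se[keep]
        w <- se - ss
        segStart[[chrom]] <- ss
        segEnd[[chrom]] <- se
        segOffset[[chrom]] <- c(0, cumsum(w))[seq_along(w)]
        maskedLength[[chrom]] <- sum(w)
    }
    new("GapMask", segStart = segStart, segEnd = segEnd,
        segOffset = segOffset, maskedLength = maskedLength)
}

#' @describeIn GapMask-class Map 0-based reference positions on one
#'   chromosome to masked coordinates. Positions inside gaps map to `NA`.
#' @param chrom Chromosome name (scalar).
#' @export
setMethod("mapToMasked", c("GapMask", "numeric"),
    function(mask, x, chrom) {
        ss <- mask@segStart[[chrom]]
        if (is.null(ss)) stop("unknown chromosome: ", chrom)
        se <- mask@segEnd[[chrom]]
        off <- mask@segOffset[[chrom]]
        j <- findInterval(x, ss)
        ok <- j >= 1L & x < se[pmax(j, 1L)] & x >= 0
        out <- rep(NA_real_, length(x))
        out[ok] <- off[j[ok]] + (x[ok] - ss[j[ok]])
        out
    })

#' @describeIn GapMask-class Inverse map: masked coordinates back to
#'   0-based reference positions.
#' @export
setMethod("mapFromMasked", c("GapMask", "numeric"),
    function(mask, x, chrom) {
        off <- mask@segOffset[[chrom]]
        if (is.null(off)) stop("unknown chromosome: ", chrom)
        ss <- mask@segStart[[chrom]]
        L <- mask@maskedLength[[chrom]]
        out <- rep(NA_real_, length(x))
        ok <- x >= 0 & x < L
        j <- findInterval(x[ok], off)
        out[ok] <- ss[j] + (x[ok] - off[j])
        out
    })

#' @describeIn GapMask-class Non-gap (masked) length per chromosome.
#' @export
maskedLengths <- function(mask) mask@maskedLength

# Map 0-based half-open intervals (data.frame chrom/start/end with an
# `id` column) into masked space. Intervals are intersected with non-gap
# segments; an interval fully inside a gap is dropped with a warning.
# Features may split into several masked pieces sharing an id; intervals
# straddling a gap are closed over the removed bases (features) so their
# masked pieces are contiguous.
maskIntervals <- function(mask, df) {
    out <- vector("list", length(mask@maskedLength))
    names(out) <- names(mask@maskedLength)
    dropped <- 0L
    for (chrom in unique(df$chrom)) {
        d <- df[df$chrom == chrom, , drop = FALSE]
        ss <- mask@segStart[[chrom]]
        if (is.null(ss)) stop("unknown chromosome: ", chrom)
        se <- mask@segEnd[[chrom]]
        off <- mask@segOffset[[chrom]]
        res <- list()
        for (i in seq_len(nrow(d))) {
            s <- d$start[i]; e <- d$end[i]
            hit <- which(se > s & ss < e)
            if (!length(hit)) { dropped <- dropped + 1L; next }
            ms <- off[hit] + pmax(s, ss[hit]) - ss[hit]
            me <- off[hit] + pmin(e, se[hit]) - ss[hit]
            res[[length(res) + 1L]] <-
                data.frame(start = ms, end = me, id = d$id[i])
        }
        out[[chrom]] <- if (length(res)) do.call(rbind, res) else
            data.frame(start = numeric(0), end = numeric(0),
                       id = character(0))
    }
    if (dropped > 0L)
        warning(dropped, " interval(s) fully inside gaps were dropped")
    out
}
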