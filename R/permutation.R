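#' Circularly shift SCE intervals in masked space
#'
#' Advances every SCE interval start by `n` bases on its own chromosome,
#' modulo the masked (gap-excluded) chromosome length, as if the
#' chromosome were circular. Interval length is preserved; an interval
#' wrapping the origin is split into two pieces that share the same `id`
#' so that it is counted once in overlap statistics. Per-chromosome SCE
#' counts are invariant under any shift.
#'
#' @param msces Named list (per chromosome) of data.frames with masked
#'   `start`, `end`, `id`, as produced by the internal gap-masking step.
#' @param n Shift in bp (\code{>= 0}).
#' @param maskedLen Named vector of masked chromosome lengths.
#' @return Shifted list in the same format.
#' @keywords internal
shiftMaskedSCEs <- function(msces, n, maskedLen) {
    stopifnot(n >= 0)
    out <- msces
    for (chrom in names(msces)) {
        d <- msces[[chrom]]
        if (!nrow(d)) next
        L <- maskedLen[[chrom]]
        w <- d$end - d$start
        s <- (d$start + n) %% L
        e <- s + w
        wrap <- e > L
        if (any(wrap)) {
            dw <- d[wrap, , drop = FALSE]
            sw <- s[wrap]; ew <- e[wrap]
            d2 <- rbind(
                data.frame(start = s[!wrap], end = e[!wrap],
                           id = d$id[!wrap]),
                data.frame(start = sw, end = L, id = dw$id),
                data.frame(start = 0, end = ew - L, id = dw$id))
        } else {
            d2 <- data.frame(start = s, end = e, id = d$id)
        }
        out[[chrom]] <- d2
    }
    out
}

# Count distinct SCE ids with >= 1 bp intersection with a reduced,
# sorted track (list per chromosome of start/end vectors). Half-open
# intervals; abutting does not overlap.
countMaskedOverlaps <- function(msces, mtrack) {
    ids <- character(0)
    for (chrom in names(msces)) {
        d <- msces[[chrom]]
        t <- mtrack[[chrom]]
        if (is.null(t) || !nrow(d) || !nrow(t)) next
        # track intervals sorted, non-overlapping: an SCE [s, e) overlaps
        # iff the last track start < e has end > s
        j <- findInterval(d$end - 0.5, t$start)
        hit <- j >= 1L & t$end[pmax(j, 1L)] > d$start
        ids <- c(ids, d$id[hit])
    }
    length(unique(ids))
}

# Any-overlap indicator of half-open query intervals [s, e) against a
# sorted non-overlapping half-open track (ts, te).
overlapAny <- function(s, e, ts, te) {
    if (!length(ts)) return(rep(FALSE, length(s)))
    j <- findInterval(e - 0.5, ts)
    j >= 1L & te[pmax(j, 1L)] > s
}

# Shift all masked SCE pieces by n (circular per chromosome) and count
# distinct SCE ids overlapping the masked track. Wrapped pieces are
# evaluated as two sub-intervals but contribute to the same id.
permShiftCount <- function(pc, nIds, n) {
    hit <- logical(nIds)
    for (ch in pc) {
        if (!length(ch$s0) || !length(ch$ts)) next
        L <- ch$L
        s <- (ch$s0 + n) %% L
        e <- s + ch$w
        ov <- overlapAny(s, pmin(e, L), ch$ts, ch$te)
        wrapped <- which(e > L)
        if (length(wrapped))
            ov[wrapped] <- ov[wrapped] |
                overlapAny(rep(0, length(wrapped)), e[wrapped] - L,
                           ch$ts, ch$te)
        hit[ch$idIdx[ov]] <- TRUE
    }
    sum(hit)
}

#' Count SCE intervals overlapping a feature track
#'
#' Number of SCE intervals intersecting at least one feature interval by
#' at least one base; each SCE is counted at most once. Intervals are
#' half-open, so abutting intervals do not overlap.
#'
#' @param sces,track [GenomicRanges::GRanges] in the same coordinate
#'   space.
#' @return Integer count.
#' @export
countSCEOverlaps <- function(sces, track) {
    sum(countOverlaps(sces, track, ignore.strand = TRUE) > 0L)
}

#' Gap-aware circular-shift permutation test for SCE enrichment
#'
#' Tests whether a set of SCE intervals overlaps a genomic feature track
#' more (or less) often than expected by chance. All annotated assembly
#' gaps are removed from the coordinate space first (non-gap segments are
#' concatenated per chromosome), so permuted SCEs can never land in a gap.
#' For each permutation a single random shift `n ~ U[shiftMin, shiftMax]`
#' is drawn and applied to **all** SCEs on their own chromosomes, modulo
#' the masked chromosome length (circular wrap). The empirical enrichment
#' p-value is the fraction of permutations whose overlap count is at
#' least the observed count, the depletion p-value the fraction at most
#' the observed count; a zero count is reported as below the floor
#' `1 / nPerm`. Enrichment is the observed overlap normalized to the
#' median permuted overlap.
#'
#' SCE intervals wider than `sizeCutoff` are treated as unlocalized and
#' removed before testing (100 kb for genes/CFS/centromeres/telomeres,
#' 10 kb for G-quadruplex motifs).
#'
#' @param sces [GenomicRanges::GRanges] of SCE uncertainty intervals
#'   (reference coordinates).
#' @param track Feature track ([GenomicRanges::GRanges]).
#' @param genome A [SyntheticGenome-class], or a named chromosome-length
#'   vector (then supply `gaps`).
#' @param param A [PermParam-class].
#' @param gaps Gap GRanges when `genome` is a plain length vector.
#' @param seed Integer seed for the shift stream.
#' @param featureName Label stored on the result.
#' @return A [PermutationResult-class].
#' @export
runPermutationTest <- function(sces, track, genome,
                               param = PermParam(), gaps = NULL,
                               seed = NULL, featureName = "feature") {
    stopifnot(is(param, "PermParam"))
    mask <- maskGaps(genome, gaps)
    mlen <- maskedLengths(mask)
    keep <- width(sces) <= param@sizeCutoff
    sces <- sces[keep]
    degenerate <- length(sces) == 0L || length(track) == 0L
    if (degenerate) {
        return(new("PermutationResult", featureName = featureName,
                   observed = 0L, permuted = integer(0),
                   enrichment = NA_real_, pEnrich = NA_real_,
                   pDeplete = NA_real_, direction = "none",
                   nSCE = length(sces), degenerate = TRUE,
                   seed = if (is.null(seed)) NA_integer_
                          else as.integer(seed)))
    }
    sdf <- grangesToDf0(sces)
    sdf$id <- sprintf("sce%06d", seq_len(nrow(sdf)))
    msces <- maskIntervals(mask, sdf)
    tdf <- grangesToDf0(reduce(track, ignore.strand = TRUE))
    tdf$id <- sprintf("f%06d", seq_len(nrow(tdf)))
    mtrackRaw <- maskIntervals(mask, tdf)
    mtrack <- lapply(mtrackRaw, function(d) {
        if (!nrow(d)) return(d)
        d <- d[order(d$start), , drop = FALSE]
        # merge touching pieces so the track stays non-overlapping
        newGrp <- cumsum(c(TRUE, d$start[-1L] > d$end[-nrow(d)]))
        data.frame(start = tapply(d$start, newGrp, min),
                   end = tapply(d$end, newGrp, max))
    })
    # flatten to plain vectors for the permutation loop
    idLevels <- sdf$id
    pc <- lapply(names(mlen), function(chrom) {
        d <- msces[[chrom]]
        t <- mtrack[[chrom]]
        if (is.null(d)) d <- data.frame(start = numeric(0),
                                        end = numeric(0),
                                        id = character(0))
        list(s0 = d$start, w = d$end - d$start,
             idIdx = match(d$id, idLevels),
             ts = if (is.null(t)) numeric(0) else t$start,
             te = if (is.null(t)) numeric(0) else t$end,
             L = mlen[[chrom]])
    })
    nIds <- length(idLevels)
    observed <- permShiftCount(pc, nIds, 0)
    permuted <- withSeed(seed, {
        vapply(seq_len(param@nPerm), function(i) {
            n <- floor(stats::runif(1, param@shiftMin,
                                    param@shiftMax + 1))
            permShiftCount(pc, nIds, n)
        }, integer(1))
    })
    pEnrich <- sum(permuted >= observed) / param@nPerm
    pDeplete <- sum(permuted <= observed) / param@nPerm
    med <- stats::median(permuted)
    enrichment <- if (med > 0) observed / med else NA_real_
    direction <- if (pEnrich < 0.05) "enriched" else
        if (pDeplete < 0.05) "depleted" else "none"
    new("PermutationResult", featureName = featureName,
        observed = as.integer(observed), permuted = permuted,
        enrichment = enrichment, pEnrich = pEnrich,
        pDeplete = pDeplete, direction = direction,
        nSCE = nrow(sdf), degenerate = is.na(enrichment),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' @describeIn PermutationResult-class Accessors for the empirical
#'   p-values and enrichment; `pEnrich`/`pDeplete` return the raw
#'   empirical fraction (0 means "below the `1/nPerm` floor").
#' @param x A `PermutationResult`.
#' @export
pEnrich <- function(x) x@pEnrich

#' @rdname PermutationResult-class
#' @export
pDeplete <- function(x) x@pDeplete

#' @rdname PermutationResult-class
#' @export
enrichment <- function(x) x@enrichment

#' @rdname PermutationResult-class
#' @export
observedOverlap <- function(x) x@observed

#' @rdname PermutationResult-class
#' @export
permutedOverlaps <- function(x) x@permuted

#' Tabulate permutation results
#'
#' @param results A list of [PermutationResult-class] objects.
#' @param bhAdjust Add Benjamini-Hochberg adjusted enrichment p-values
#'   across the tested features? Off by default: the per-feature
#'   permutation p-values are reported as-is.
#' @return data.frame with one row per feature: observed and
#'   median/mean permuted overlaps, enrichment, one-sided p-values
#'   (formatted with the `1/nPerm` floor), permutation count and seed.
#' @export
permReport <- function(results, bhAdjust = FALSE) {
    rows <- lapply(results, function(r) {
        nPerm <- length(r@permuted)
        data.frame(
            feature = r@featureName,
            nSCE = r@nSCE,
            observed = r@observed,
            medianPermuted = if (nPerm) stats::median(r@permuted)
                             else NA_real_,
            meanPermuted = if (nPerm) mean(r@permuted) else NA_real_,
            enrichment = r@enrichment,
            pEnrich = r@pEnrich,
            pDeplete = r@pDeplete,
            pEnrichLabel = if (nPerm)
                formatPermP(r@pEnrich, nPerm) else NA_character_,
            pDepleteLabel = if (nPerm)
                formatPermP(r@pDeplete, nPerm) else NA_character_,
            direction = r@direction,
            nPerm = nPerm,
            seed = r@seed,
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (bhAdjust) {
        floorP <- ifelse(out$pEnrich <= 0, 1 / pmax(out$nPerm, 1),
                         out$pEnrich)
        out$pEnrichBH <- stats::p.adjust(floorP, method = "BH")
    }
    out
}
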