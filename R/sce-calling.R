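#' Filter Strand-seq reads by mapping quality and duplicate status
#'
#' Retains exactly the non-duplicate reads with MAPQ greater than or equal
#' to `minMapq` (default 10), sorted by chromosome and position.
#'
#' @param reads data.frame with columns `chrom`, `pos` (0-based),
#'   `strand` (`"W"`/`"C"`), `mapq`, `dup`.
#' @param param An [SCEParam-class].
#' @return The filtered, sorted read table.
#' @export
filterReads <- function(reads, param = SCEParam()) {
    stopifnot(is(param, "SCEParam"))
    required <- c("chrom", "pos", "strand", "mapq", "dup")
    if (!all(required %in% names(reads)))
        stop("read table must have columns: ",
             paste(required, collapse = ", "))
    bad <- which(!reads$strand %in% c("W", "C"))
    if (length(bad))
        stop("unknown strand symbol at row(s): ",
             paste(utils::head(bad, 5), collapse = ", "))
    out <- reads[reads$mapq >= param@minMapq & !reads$dup, , drop = FALSE]
    out <- out[order(out$chrom, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Correct isolated strand-flip errors
#'
#' A single read whose `flipWindow` nearest neighbours on *each* side
#' (same chromosome) all carry the opposite strand is treated as a
#' directionality error and its strand label is inverted. Flips are
#' decided against the original labels and applied simultaneously, so the
#' result does not depend on scan order. Reads with fewer than
#' `flipWindow` neighbours on either side (chromosome ends) are never
#' flipped.
#'
#' @param reads Filtered read table, sorted by chromosome and position.
#' @param param An [SCEParam-class].
#' @return A list with the corrected table (`reads`) and the number of
#'   inverted labels (`nFlipped`).
#' @export
flipIsolatedReads <- function(reads, param = SCEParam()) {
    stopifnot(is(param, "SCEParam"))
    w <- param@flipWindow
    flip <- logical(nrow(reads))
    for (chrom in unique(reads$chrom)) {
        idx <- which(reads$chrom == chrom)
        n <- length(idx)
        if (n < 2L * w + 1L) next
        s <- ifelse(reads$strand[idx] == "C", 1L, -1L)
        cs <- c(0L, cumsum(s))
        i <- (w + 1L):(n - w)
        leftSum <- cs[i] - cs[i - w]
        rightSum <- cs[i + w + 1L] - cs[i + 1L]
        hit <- leftSum == -w * s[i] & rightSum == -w * s[i]
        flip[idx[i[hit]]] <- TRUE
    }
    reads$strand[flip] <- ifelse(reads$strand[flip] == "W", "C", "W")
    list(reads = reads, nFlipped = sum(flip))
}

#' Segment read directionality by recursive binary segmentation
#'
#' Encodes strand as +1 (Crick) / -1 (Watson) and recursively splits each
#' chromosome's read sequence at the index maximizing the absolute CUSUM
#' statistic (ties broken towards the leftmost index). A candidate
#' changepoint is accepted when (a) Fisher's exact test on the two flanks'
#' Watson/Crick counts is significant at `segAlpha`, and (b) each flank
#' carries at least `minSupport` reads of its own majority direction.
#' Adjacent segments with equal majority state are merged, so the returned
#' segments strictly alternate.
#'
#' @param reads Filtered (and flip-corrected) read table, sorted by
#'   chromosome and position.
#' @param param An [SCEParam-class].
#' @return data.frame with one row per segment: `chrom`, `firstReadPos`,
#'   `lastReadPos`, `state` (majority direction), `nStateReads`,
#'   `nOtherReads`, and the row span `firstIdx`/`lastIdx` into `reads`.
#' @export
segmentDirectionality <- function(reads, param = SCEParam()) {
    stopifnot(is(param, "SCEParam"))
    segs <- list()
    for (chrom in unique(reads$chrom)) {
        idx <- which(reads$chrom == chrom)
        x <- ifelse(reads$strand[idx] == "C", 1L, -1L)
        n <- length(x)
        if (n < 2L * param@minSupport) {
            warning("fewer than 2 x minSupport reads on ", chrom,
                    "; returning a single segment")
            bounds <- integer(0)
        } else {
            bounds <- sort(findChangepoints(x, 1L, n,
                                            param@segAlpha,
                                            param@minSupport))
        }
        starts <- c(1L, bounds + 1L)
        ends <- c(bounds, n)
        st <- vapply(seq_along(starts), function(j) {
            xx <- x[starts[j]:ends[j]]
            if (sum(xx == 1L) >= sum(xx == -1L)) "C" else "W"
        }, character(1))
        # merge adjacent segments with the same majority state
        keep <- c(TRUE, st[-1L] != st[-length(st)])
        gstart <- starts[keep]
        gend <- c(gstart[-1L] - 1L, n)
        gstate <- st[keep]
        for (j in seq_along(gstart)) {
            xx <- x[gstart[j]:gend[j]]
            nC <- sum(xx == 1L); nW <- length(xx) - nC
            segs[[length(segs) + 1L]] <- data.frame(
                chrom = chrom,
                firstReadPos = reads$pos[idx[gstart[j]]],
                lastReadPos = reads$pos[idx[gend[j]]],
                state = gstate[j],
                nStateReads = if (gstate[j] == "C") nC else nW,
                nOtherReads = if (gstate[j] == "C") nW else nC,
                firstIdx = idx[gstart[j]],
                lastIdx = idx[gend[j]],
                stringsAsFactors = FALSE)
        }
    }
    if (!length(segs))
        return(data.frame(chrom = character(0),
                          firstReadPos = numeric(0),
                          lastReadPos = numeric(0), state = character(0),
                          nStateReads = integer(0),
                          nOtherReads = integer(0),
                          firstIdx = integer(0), lastIdx = integer(0)))
    out <- do.call(rbind, segs)
    rownames(out) <- NULL
    out
}

# Recursive binary segmentation on the +/-1 signal x over [s, e].
# Returns accepted changepoint indices (boundary after index k).
findChangepoints <- function(x, s, e, alpha, minSupport) {
    len <- e - s + 1L
    if (len < 2L * minSupport) return(integer(0))
    xx <- x[s:e]
    cum <- cumsum(xx - mean(xx))
    kRel <- which.max(abs(cum[seq_len(len - 1L)]))  # leftmost maximum
    k <- s + kRel - 1L
    left <- x[s:k]
    right <- x[(k + 1L):e]
    cl <- sum(left == 1L); wl <- length(left) - cl
    cr <- sum(right == 1L); wr <- length(right) - cr
    if (max(cl, wl) < minSupport || max(cr, wr) < minSupport)
        return(integer(0))
    p <- stats::fisher.test(matrix(c(cl, wl, cr, wr), nrow = 2L))$p.value
    # the split index is chosen as the CUSUM maximum over len - 1
    # candidates, so the exact test is Bonferroni-corrected for that
    # selection; alpha is the per-segment level
    if (p >= alpha / (len - 1L)) return(integer(0))
    c(findChangepoints(x, s, k, alpha, minSupport), k,
      findChangepoints(x, k + 1L, e, alpha, minSupport))
}

#' Call SCE events from directionality segments
#'
#' Emits one sister-chromatid-exchange event per adjacent pair of
#' alternating segments, provided both segments carry at least
#' `minSupport` reads of their majority direction. The event interval is
#' the 0-based half-open range from the position of the last
#' majority-strand read of the left segment to the position of the first
#' majority-strand read of the right segment - the uncertainty interval
#' between the last and first informative reads.
#'
#' When `flipRate` is positive, the changepoint location is treated as
#' uncertain under a strand-flip error model: every read assignment
#' (split) near the segment boundary is scored by its number of
#' misclassified reads, splits are weighted by
#' `(flipRate / (1 - flipRate))^cost`, and the interval is taken between
#' the last left-majority read before - and the first right-majority
#' read after - the smallest set of splits holding at least
#' `1 - segAlpha` of that mass. With `flipRate = 0` (the default) only
#' the minimal-misclassification splits are included, which on clean
#' data is exactly the last-read/first-read interval.
#'
#' @param segments Output of [segmentDirectionality()].
#' @param reads The read table the segments were computed from.
#' @param param An [SCEParam-class].
#' @param libraryId Library label stored on each event.
#' @param flipRate Estimated residual strand-flip error rate used to
#'   widen the uncertainty interval (see Details); [callSCEsFromReads()]
#'   passes the rate estimated by the flip-correction step.
#' @return A [GenomicRanges::GRanges] of events with metadata columns
#'   `libraryId`, `leftSupport`, `rightSupport`. Start/end encode the
#'   0-based half-open interval in the usual GRanges 1-based way
#'   (`start(gr) - 1` is the BED start).
#' @export
callSCEs <- function(segments, reads, param = SCEParam(),
                     libraryId = "lib1", flipRate = 0) {
    stopifnot(is(param, "SCEParam"), flipRate >= 0, flipRate < 0.5)
    ev <- list()
    if (nrow(segments) >= 2L) {
        for (i in seq_len(nrow(segments) - 1L)) {
            a <- segments[i, ]; b <- segments[i + 1L, ]
            if (a$chrom != b$chrom) next
            if (a$nStateReads < param@minSupport ||
                b$nStateReads < param@minSupport) next
            bnd <- refineBoundary(reads, a, b, flipRate,
                                  param@segAlpha)
            if (is.null(bnd)) next  # degenerate (interleaved boundary)
            ev[[length(ev) + 1L]] <- data.frame(
                chrom = a$chrom, start = bnd[1L], end = bnd[2L],
                leftSupport = a$nStateReads,
                rightSupport = b$nStateReads,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(ev)) {
        gr <- GRanges()
        gr$libraryId <- character(0)
        gr$leftSupport <- integer(0)
        gr$rightSupport <- integer(0)
        return(gr)
    }
    df <- do.call(rbind, ev)
    gr <- df0ToGRanges(df, extraCols = c("leftSupport", "rightSupport"))
    gr$libraryId <- libraryId
    gr[, c("libraryId", "leftSupport", "rightSupport")]
}

# Event-interval endpoints for one adjacent segment pair (a left, b
# right). Candidate splits within a window around the segment boundary
# are scored by misclassification cost; the credible set of splits
# (mass >= 1 - alpha under the flip-error model, or the exact minimal-
# cost set when flipRate = 0) determines the interval: from the last
# a-state read before the leftmost retained split to the first b-state
# read after the rightmost retained split. Returns c(left, right) in
# 0-based half-open coordinates, or NULL when degenerate.
refineBoundary <- function(reads, a, b, flipRate, alpha,
                           window = 12L) {
    ia <- max(a$firstIdx, a$lastIdx - window + 1L):a$lastIdx
    ib <- b$firstIdx:min(b$lastIdx, b$firstIdx + window - 1L)
    idx <- c(ia, ib)
    s <- reads$strand[idx]
    nA <- length(ia)
    len <- length(idx)
    isB <- s == b$state
    # cost(j) = misclassified reads when the changepoint is after the
    # j-th window read, j = 0..len
    cumB <- c(0L, cumsum(isB))          # B-reads at or before j
    cumA <- c(0L, cumsum(!isB))         # A-reads at or before j
    cost <- cumB[0:len + 1L] + (cumA[len + 1L] - cumA[0:len + 1L])
    cmin <- min(cost)
    if (flipRate > 0) {
        r <- flipRate / (1 - flipRate)
        mass <- r^(cost - cmin)
        keepLevels <- sort(unique(cost))
        total <- sum(mass)
        acc <- 0; cut <- cmin
        for (cl in keepLevels) {
            acc <- acc + sum(mass[cost == cl])
            cut <- cl
            if (acc / total >= 1 - alpha) break
        }
        S <- which(cost <= cut) - 1L
    } else {
        S <- which(cost == cmin) - 1L
    }
    jL <- min(S); jR <- max(S)
    # last a-state read at window index <= jL (search back into the
    # whole left segment if the window is exhausted)
    leftPos <- NA_real_
    cand <- idx[seq_len(len) <= jL]
    cand <- cand[reads$strand[cand] == a$state]
    if (length(cand)) {
        leftPos <- reads$pos[max(cand)]
    } else {
        pre <- a$firstIdx:a$lastIdx
        pre <- pre[pre < min(idx) & reads$strand[pre] == a$state]
        if (length(pre)) leftPos <- reads$pos[max(pre)]
    }
    rightPos <- NA_real_
    cand <- idx[seq_len(len) > jR]
    cand <- cand[reads$strand[cand] == b$state]
    if (length(cand)) {
        rightPos <- reads$pos[min(cand)]
    } else {
        post <- b$firstIdx:b$lastIdx
        post <- post[post > max(idx) & reads$strand[post] == b$state]
        if (length(post)) rightPos <- reads$pos[min(post)]
    }
    if (is.na(leftPos) || is.na(rightPos) || leftPos >= rightPos)
        return(NULL)
    c(leftPos, rightPos)
}

#' Localize SCEs in one haploid Strand-seq library
#'
#' Convenience wrapper chaining [filterReads()], [flipIsolatedReads()],
#' [segmentDirectionality()] and [callSCEs()].
#'
#' @inheritParams filterReads
#' @param libraryId Library label.
#' @return A list with `events` (GRanges), `segments`, the filtered
#'   `reads`, and `counts` (reads retained at each stage, flips applied).
#' @export
callSCEsFromReads <- function(reads, param = SCEParam(),
                              libraryId = "lib1") {
    filtered <- filterReads(reads, param)
    flipped <- flipIsolatedReads(filtered, param)
    segments <- segmentDirectionality(flipped$reads, param)
    flipRate <- flipped$nFlipped / max(1L, nrow(filtered))
    events <- callSCEs(segments, flipped$reads, param, libraryId,
                       flipRate = flipRate)
    list(events = events, segments = segments, reads = flipped$reads,
         counts = c(input = nrow(reads), filtered = nrow(filtered),
                    flipped = flipped$nFlipped,
                    segments = nrow(segments), events = length(events)))
}

#' Flag clonal (recurrent) events across libraries
#'
#' An event location observed at the same interval (within `matchSlop` bp
#' on both endpoints) in strictly more than `clonalFraction` of the
#' libraries is a stable rearrangement of the cell line rather than a
#' per-cell SCE; such events are flagged recurrent and removed from the
#' non-recurrent output.
#'
#' @param events [GenomicRanges::GRanges] of events from all libraries,
#'   carrying a `libraryId` metadata column.
#' @param nLibraries Total number of libraries screened.
#' @param clonalFraction Fraction threshold (strict; default 0.25, i.e.
#'   recurrence in more than 25% of libraries).
#' @param matchSlop Endpoint tolerance in bp for "same location"
#'   (default 0: exact).
#' @return A list of GRanges: `recurrent` and `nonRecurrent`.
#' @export
filterClonalEvents <- function(events, nLibraries,
                               clonalFraction = 0.25, matchSlop = 0L) {
    if (nLibraries <= 0L) stop("nLibraries must be positive")
    if (!"libraryId" %in% names(mcols(events)))
        stop("events must carry a libraryId metadata column")
    if (!length(events))
        return(list(recurrent = events, nonRecurrent = events))
    if (matchSlop == 0L) {
        key <- paste(seqnames(events), start(events), end(events))
        cluster <- match(key, unique(key))
    } else {
        o <- order(as.factor(seqnames(events)), start(events),
                   end(events))
        cluster <- integer(length(events))
        cid <- 0L
        refS <- refE <- -Inf; refChrom <- ""
        for (i in o) {
            ch <- as.character(seqnames(events))[i]
            if (ch != refChrom ||
                abs(start(events)[i] - refS) > matchSlop ||
                abs(end(events)[i] - refE) > matchSlop) {
                cid <- cid + 1L
                refChrom <- ch
                refS <- start(events)[i]; refE <- end(events)[i]
            }
            cluster[i] <- cid
        }
    }
    nLibs <- vapply(split(events$libraryId, cluster),
                    function(v) length(unique(v)), integer(1))
    clonal <- cluster %in% as.integer(names(nLibs)[
        nLibs > clonalFraction * nLibraries])
    list(recurrent = events[clonal], nonRecurrent = events[!clonal])
}

#' Score SCE calls against planted ground truth
#'
#' A call is a true positive when its uncertainty interval (closed on both
#' ends) contains a planted breakpoint on the same chromosome; a planted
#' breakpoint is recovered when at least one call contains it.
#'
#' @param events [GenomicRanges::GRanges] of calls.
#' @param breakpoints data.frame `chrom`, `pos` (0-based) of planted
#'   breakpoints.
#' @return A list: `precision`, `recall`, `nCalls`, `nTruth`.
#' @export
evaluateSCECalls <- function(events, breakpoints) {
    nCalls <- length(events)
    nTruth <- nrow(breakpoints)
    if (nCalls == 0L)
        return(list(precision = NA_real_, recall = if (nTruth) 0 else
            NA_real_, nCalls = 0L, nTruth = nTruth))
    truthGR <- GRanges(breakpoints$chrom,
                       IRanges(breakpoints$pos + 1, breakpoints$pos + 1))
    # closed containment: widen calls by 1 bp on the right
    callGR <- GRanges(seqnames(events),
                      IRanges(start(events), end(events) + 1))
    hits <- findOverlaps(callGR, truthGR)
    tp <- length(unique(S4Vectors::queryHits(hits)))
    rec <- length(unique(S4Vectors::subjectHits(hits)))
    list(precision = tp / nCalls,
         recall = if (nTruth) rec / nTruth else NA_real_,
         nCalls = nCalls, nTruth = nTruth)
}
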