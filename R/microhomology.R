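#' Prepare a common-fragile-site track for containment analysis
#'
#' Removes any CFS interval fully enveloped within another CFS interval
#' (when two annotated sites nest, only the enclosing one is kept;
#' duplicated intervals are collapsed to one), and restricts the track to
#' autosomes.
#'
#' @param cfs [GenomicRanges::GRanges] of CFS intervals.
#' @param autosomesOnly Drop non-autosomal chromosomes (names not of the
#'   form `chrN`/`N` with numeric `N`)? Default `TRUE`.
#' @return The pruned, sorted track.
#' @export
prepareCFSTrack <- function(cfs, autosomesOnly = TRUE) {
    if (!length(cfs)) return(cfs)
    out <- cfs
    if (autosomesOnly)
        out <- out[isAutosomeName(as.character(seqnames(out)))]
    if (!length(out)) return(sort(out))
    out <- unique(out)
    hits <- findOverlaps(out, out, type = "within",
                         ignore.strand = TRUE)
    hits <- hits[S4Vectors::queryHits(hits) !=
                 S4Vectors::subjectHits(hits)]
    enveloped <- unique(S4Vectors::queryHits(hits))
    if (length(enveloped)) out <- out[-enveloped]
    sort(out)
}

#' Is a deletion fully contained in a single CFS interval?
#'
#' `TRUE` iff the entire deletion interval lies within one CFS interval;
#' a deletion straddling a CFS boundary, or spanning two adjacent CFSs
#' while inside neither alone, is not contained.
#'
#' @param dels Deletions: a [GenomicRanges::GRanges], or a data.frame
#'   with `chrom`, `start`, `end` (0-based half-open).
#' @param cfs Prepared CFS track (see [prepareCFSTrack()]).
#' @return Logical vector, one flag per deletion.
#' @export
deletionInCFS <- function(dels, cfs) {
    if (is.data.frame(dels)) dels <- df0ToGRanges(dels)
    countOverlaps(dels, cfs, type = "within",
                  ignore.strand = TRUE) >= 1L
}

#' Junction microhomology of a deletion from the reference sequence
#'
#' For each deletion `[start, end)` the forward-side microhomology
#' `mhFwd` is the length of the longest common prefix of the deleted
#' sequence and the sequence starting at `end`; the reverse-side
#' `mhRev` is the longest common suffix of the deleted sequence and the
#' sequence ending at `start`. The reported `mhLength` is
#' `mhFwd + mhRev`, capped at the deletion length - the junction between
#' the retained flanks is identical under either one-sided convention,
#' and both one-sided values are kept so alternative summaries can be
#' derived. Comparison is case-insensitive and terminates at the first
#' `N`. Deletions on chromosomes missing from the reference are flagged
#' `missing` and should be excluded from downstream fractions.
#'
#' @param genome A [SyntheticGenome-class] with sequence, a named
#'   [Biostrings::DNAStringSet], or a path to a FASTA file.
#' @param dels data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param maxProbe Maximum one-sided probe length in bp (default 50).
#' @return `dels` with added columns `mhFwd`, `mhRev`, `mhLength`,
#'   `missing`.
#' @export
microhomologyLength <- function(genome, dels, maxProbe = 50L) {
    seqs <- if (is(genome, "SyntheticGenome")) genomeSequence(genome)
            else if (is.character(genome) && length(genome) == 1L)
                readDNAStringSet(genome)
            else genome
    if (is.null(seqs)) stop("reference sequence required")
    if (is.character(names(seqs)))
        names(seqs) <- sub("\\s.*$", "", names(seqs))
    chromStrings <- as.list(toupper(as.character(seqs)))
    n <- nrow(dels)
    mhFwd <- mhRev <- integer(n)
    missing <- logical(n)
    for (i in seq_len(n)) {
        x <- chromStrings[[dels$chrom[i]]]
        if (is.null(x)) { missing[i] <- TRUE; next }
        s <- dels$start[i]; e <- dels$end[i]
        if (s >= e) stop("deletion with start >= end at row ", i)
        len <- e - s
        probe <- min(maxProbe, len)
        chromLen <- nchar(x)
        # forward: deleted prefix vs sequence starting at the 3' junction
        delFwd <- substr(x, s + 1, s + probe)
        after <- substr(x, e + 1, min(e + probe, chromLen))
        mhFwd[i] <- commonPrefixLen(delFwd, after)
        # reverse: deleted suffix vs sequence ending at the 5' junction
        delRev <- substr(x, max(e - probe + 1, 1), e)
        before <- substr(x, max(s - probe + 1, 1), s)
        mhRev[i] <- commonPrefixLen(reverseString(delRev),
                                    reverseString(before))
        if (mhFwd[i] + mhRev[i] > len) {
            # cap combined microhomology at the deletion length
            mhRev[i] <- len - mhFwd[i]
        }
    }
    dels$mhFwd <- mhFwd
    dels$mhRev <- mhRev
    dels$mhLength <- mhFwd + mhRev
    dels$missing <- missing
    dels
}

#' Compare HRD and HRP deletion cohorts
#'
#' Per sample, computes (a) the fraction of its deletions fully contained
#' in a single CFS and (b) among those CFS deletions, the fraction with
#' junction microhomology at least `mhMin` bp (default 2, the signature
#' of polymerase-theta-mediated end joining). Group differences are
#' tested per metric with a two-sided Wilcoxon rank-sum test on the
#' per-sample values, Benjamini-Hochberg-corrected across metrics; a
#' pooled two-proportion test on deletion counts is reported alongside,
#' clearly labelled, since the per-sample and pooled summaries answer
#' slightly different questions. Samples with zero CFS deletions have an
#' undefined MH fraction and are excluded from that metric (their count
#' is recorded).
#'
#' @param dels data.frame with columns `sample`, `group` (`HRD`/`HRP`),
#'   `inCFS` (logical), `mhLength` (bp).
#' @param mhMin Microhomology threshold in bp.
#' @return A [CohortComparison-class].
#' @export
cohortCompare <- function(dels, mhMin = 2L) {
    stopifnot(all(c("sample", "group", "inCFS", "mhLength") %in%
                  names(dels)))
    if (mhMin < 0L) stop("mhMin must be >= 0")
    groups <- unique(dels$group)
    if (length(groups) != 2L)
        stop("exactly two groups required, got: ",
             paste(groups, collapse = ", "))
    sampleF <- factor(dels$sample)
    lev <- levels(sampleF)
    nDeletions <- tabulate(sampleF, nbins = length(lev))
    nCFS <- as.vector(rowsum(as.numeric(dels$inCFS), sampleF))
    nMH <- as.vector(rowsum(as.numeric(dels$inCFS &
                                       dels$mhLength >= mhMin),
                            sampleF))
    perSample <- data.frame(
        sample = lev,
        group = dels$group[match(lev, dels$sample)],
        nDeletions = nDeletions,
        nCFS = as.integer(nCFS),
        fracCFS = nCFS / nDeletions,
        fracMH = ifelse(nCFS > 0, nMH / nCFS, NA_real_),
        stringsAsFactors = FALSE)
    if (any(tabulate(factor(perSample$group)) < 2L))
        stop("need at least 2 samples per group")
    nNoCFS <- sum(is.na(perSample$fracMH))
    if (nNoCFS)
        message(nNoCFS, " sample(s) with zero CFS deletions excluded ",
                "from the MH metric")

    boxStats <- function(v) {
        v <- v[!is.na(v)]
        q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
        iqr <- q[2] - q[1]
        c(mean = mean(v), q25 = q[1], q75 = q[2],
          whiskerLow = min(v[v >= q[1] - 1.5 * iqr]),
          whiskerHigh = max(v[v <= q[2] + 1.5 * iqr]))
    }
    groupSummary <- do.call(rbind, lapply(split(perSample,
                                                perSample$group),
        function(g) {
            d <- dels[dels$group == g$group[1], , drop = FALSE]
            cfsD <- d[d$inCFS, , drop = FALSE]
            bCFS <- boxStats(g$fracCFS)
            bMH <- boxStats(g$fracMH)
            data.frame(group = g$group[1],
                       nSamples = nrow(g),
                       nDeletions = nrow(d),
                       pooledPctCFS = 100 * nrow(cfsD) / nrow(d),
                       pooledPctMH = if (nrow(cfsD)) 100 *
                           mean(cfsD$mhLength >= mhMin) else NA_real_,
                       meanFracCFS = bCFS[["mean"]],
                       q25FracCFS = bCFS[["q25"]],
                       q75FracCFS = bCFS[["q75"]],
                       meanFracMH = bMH[["mean"]],
                       q25FracMH = bMH[["q25"]],
                       q75FracMH = bMH[["q75"]],
                       stringsAsFactors = FALSE)
        }))
    rownames(groupSummary) <- NULL

    g1 <- perSample[perSample$group == groups[1], ]
    g2 <- perSample[perSample$group == groups[2], ]
    wCFS <- stats::wilcox.test(g1$fracCFS, g2$fracCFS,
                               alternative = "two.sided", exact = FALSE)
    wMH <- stats::wilcox.test(g1$fracMH[!is.na(g1$fracMH)],
                              g2$fracMH[!is.na(g2$fracMH)],
                              alternative = "two.sided", exact = FALSE)
    pAdj <- stats::p.adjust(c(wCFS$p.value, wMH$p.value),
                            method = "BH")
    # pooled two-proportion comparison on deletion counts
    d1 <- dels[dels$group == groups[1], ]
    d2 <- dels[dels$group == groups[2], ]
    propCFS <- stats::prop.test(c(sum(d1$inCFS), sum(d2$inCFS)),
                                c(nrow(d1), nrow(d2)))
    c1 <- d1[d1$inCFS, ]; c2 <- d2[d2$inCFS, ]
    propMH <- if (nrow(c1) && nrow(c2))
        stats::prop.test(c(sum(c1$mhLength >= mhMin),
                           sum(c2$mhLength >= mhMin)),
                         c(nrow(c1), nrow(c2))) else NULL
    tests <- data.frame(
        metric = c("fracCFS", "fracMH"),
        test = "Wilcoxon rank-sum (per-sample, two-sided)",
        p = c(wCFS$p.value, wMH$p.value),
        pBH = pAdj,
        pooledTest = "two-proportion (pooled counts)",
        pPooled = c(propCFS$p.value,
                    if (is.null(propMH)) NA_real_ else propMH$p.value),
        stringsAsFactors = FALSE)
    new("CohortComparison", perSample = perSample,
        groupSummary = groupSummary, tests = tests,
        mhMin = as.integer(mhMin))
}

#' @describeIn CohortComparison-class Accessors.
#' @param x A `CohortComparison`.
#' @export
perSampleMetrics <- function(x) x@perSample

#' @rdname CohortComparison-class
#' @export
groupSummary <- function(x) x@groupSummary

#' @rdname CohortComparison-class
#' @export
cohortTests <- function(x) x@tests
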