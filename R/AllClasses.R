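#' @import methods
#' @importFrom BiocGenerics sort unique
#' @importFrom S4Vectors metadata isSorted
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols
#'   mcols<- granges reduce findOverlaps countOverlaps coverage
#' @importFrom IRanges IRanges ranges slice
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels seqnames
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   subseq complement
#' @importClassesFrom Biostrings DNAStringSet DNAString
NULL

setClassUnion("DNAStringSetOrNULL", c("DNAStringSet", "NULL"))

#' SyntheticGenome: a simulated reference genome
#'
#' Container for a simulated genome: chromosome names and lengths, assembly
#' gap intervals, and (optionally) the nucleotide sequence. Coordinates are
#' 0-based half-open throughout the package, matching BED.
#'
#' @slot seqinfo A [GenomeInfoDb::Seqinfo] with chromosome names and lengths.
#' @slot gaps A [GenomicRanges::GRanges] of assembly gaps (0-based half-open
#'   encoded as start = BED start + 1 internally, i.e. standard GRanges).
#' @slot sequence A [Biostrings::DNAStringSet] with one entry per chromosome,
#'   or `NULL` when sequence was not simulated.
#' @slot seed Integer seed the genome was generated with (for provenance).
#'
#' @seealso [simulateGenome()]
#' @export
setClass("SyntheticGenome",
    representation(
        seqinfo = "Seqinfo",
        gaps = "GRanges",
        sequence = "DNAStringSetOrNULL",
        seed = "integer"
    )
)

setValidity("SyntheticGenome", function(object) {
    msg <- character()
    sl <- seqlengths(object@seqinfo)
    if (length(sl) == 0L || any(is.na(sl)) || any(sl <= 0L))
        msg <- c(msg, "chromosome lengths must be positive and known")
    if (length(object@gaps)) {
        g <- object@gaps
        bad <- !as.character(seqnames(g)) %in% names(sl)
        if (any(bad)) {
            msg <- c(msg, "gaps on unknown chromosomes")
        } else {
            lim <- sl[as.character(seqnames(g))]
            if (any(start(g) < 1L) || any(end(g) > lim))
                msg <- c(msg, "gaps extend beyond chromosome bounds")
            red <- reduce(g)
            if (length(red) != length(g) || sum(width(red)) != sum(width(g)))
                msg <- c(msg, "gaps must be non-overlapping")
        }
    }
    if (!is.null(object@sequence)) {
        if (!identical(sort(names(object@sequence)), sort(names(sl))))
            msg <- c(msg, "sequence names must match chromosome names")
        else if (!all(Biostrings::width(object@sequence)[
                match(names(sl), names(object@sequence))] == unname(sl)))
            msg <- c(msg, "sequence lengths must equal chromosome lengths")
    }
    if (length(msg)) msg else TRUE
})

#' SCEParam: parameters for SCE calling
#'
#' Thresholds applied when localizing sister chromatid exchanges in a
#' haploid Strand-seq library.
#'
#' @slot minMapq Minimum mapping quality; reads with MAPQ below this are
#'   discarded (default 10).
#' @slot minSupport Minimum number of majority-direction reads required on
#'   each side of a putative SCE site (default 3).
#' @slot flipWindow Number of nearest neighbours on each side that must all
#'   carry the opposite strand for an isolated read to be treated as a
#'   strand-flip error and inverted (default 3). The notion of a single
#'   read "embedded within an extended region" of opposite directionality
#'   is not a fixed-width definition; the default mirrors the 3-read
#'   support threshold and is configurable.
#' @slot segAlpha Significance level of the two-flank directionality test
#'   used to accept a candidate changepoint during recursive binary
#'   segmentation (default 0.01).
#'
#' @seealso [callSCEs()], [segmentDirectionality()]
#' @export
setClass("SCEParam",
    representation(
        minMapq = "integer",
        minSupport = "integer",
        flipWindow = "integer",
        segAlpha = "numeric"
    ),
    prototype(
        minMapq = 10L,
        minSupport = 3L,
        flipWindow = 3L,
        segAlpha = 0.01
    )
)

setValidity("SCEParam", function(object) {
    msg <- character()
    if (object@minMapq < 0L) msg <- c(msg, "minMapq must be >= 0")
    if (object@minSupport < 1L) msg <- c(msg, "minSupport must be >= 1")
    if (object@flipWindow < 1L) msg <- c(msg, "flipWindow must be >= 1")
    if (object@segAlpha <= 0 || object@segAlpha >= 1)
        msg <- c(msg, "segAlpha must lie in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' @describeIn SCEParam Constructor.
#' @param minMapq,minSupport,flipWindow,segAlpha See slot documentation.
#' @return `SCEParam()` returns an `SCEParam` object.
#' @export
SCEParam <- function(minMapq = 10L, minSupport = 3L, flipWindow = 3L,
                     segAlpha = 0.01) {
    new("SCEParam", minMapq = as.integer(minMapq),
        minSupport = as.integer(minSupport),
        flipWindow = as.integer(flipWindow), segAlpha = segAlpha)
}

#' PermParam: parameters for the circular-shift permutation test
#'
#' @slot nPerm Number of permutations (default 1000; 10000 is used for
#'   higher-resolution p-values).
#' @slot shiftMin,shiftMax Bounds (bp) of the uniform distribution the
#'   per-permutation shift is drawn from; defaults 2 Mb and 50 Mb so that
#'   shifts are never small-scale local moves.
#' @slot sizeCutoff Maximum SCE uncertainty-interval width (bp) admitted to
#'   the test; wider intervals are considered unlocalized. Default 100 kb
#'   (use 10 kb for G-quadruplex motif tests).
#'
#' @seealso [runPermutationTest()]
#' @export
setClass("PermParam",
    representation(
        nPerm = "integer",
        shiftMin = "numeric",
        shiftMax = "numeric",
        sizeCutoff = "numeric"
    ),
    prototype(
        nPerm = 1000L,
        shiftMin = 2e6,
        shiftMax = 5e7,
        sizeCutoff = 1e5
    )
)

setValidity("PermParam", function(object) {
    msg <- character()
    if (object@nPerm < 1L) msg <- c(msg, "nPerm must be >= 1")
    if (!(object@shiftMin > 0 && object@shiftMin < object@shiftMax))
        msg <- c(msg, "need 0 < shiftMin < shiftMax")
    if (object@sizeCutoff <= 0) msg <- c(msg, "sizeCutoff must be positive")
    if (length(msg)) msg else TRUE
})

#' @describeIn PermParam Constructor.
#' @param nPerm,shiftMin,shiftMax,sizeCutoff See slot documentation.
#' @return `PermParam()` returns a `PermParam` object.
#' @export
PermParam <- function(nPerm = 1000L, shiftMin = 2e6, shiftMax = 5e7,
                      sizeCutoff = 1e5) {
    new("PermParam", nPerm = as.integer(nPerm), shiftMin = shiftMin,
        shiftMax = shiftMax, sizeCutoff = sizeCutoff)
}

#' GapMask: gap-excluded (masked) coordinate space
#'
#' Per-chromosome bijection between reference coordinates restricted to
#' non-gap bases and a concatenated "masked" coordinate space in which the
#' non-gap segments of each chromosome are juxtaposed. Circular shifts in
#' masked space can therefore never place an interval inside an assembly
#' gap.
#'
#' @slot segStart,segEnd Named lists (one element per chromosome) of the
#'   0-based half-open non-gap segments in reference coordinates.
#' @slot segOffset Named list of cumulative masked-space offsets of those
#'   segments.
#' @slot maskedLength Named numeric vector: masked (non-gap) length per
#'   chromosome.
#'
#' @seealso [maskGaps()], [mapToMasked()], [mapFromMasked()]
#' @export
setClass("GapMask",
    representation(
        segStart = "list",
        segEnd = "list",
        segOffset = "list",
        maskedLength = "numeric"
    )
)

#' PermutationResult: outcome of a circular-shift enrichment test
#'
#' @slot featureName Label of the feature track tested.
#' @slot observed Observed number of SCE intervals overlapping the track.
#' @slot permuted Integer vector (length `nPerm`) of permuted overlap counts.
#' @slot enrichment Observed overlap normalized to the median permuted
#'   overlap; `NA` (with `degenerate = TRUE`) when the median is zero.
#' @slot pEnrich,pDeplete Empirical one-sided p-values: the fraction of
#'   permutations with overlap at least (resp. at most) the observed value.
#'   A zero count is reported as below the p-value floor `1 / nPerm`.
#' @slot direction `"enriched"`, `"depleted"`, or `"none"` at the 0.05
#'   level.
#' @slot nSCE Number of SCE intervals entering the test (after the size
#'   cutoff).
#' @slot degenerate TRUE when the test was degenerate (no SCEs, empty
#'   track, or zero permuted median).
#' @slot seed Seed used for the permutation stream.
#'
#' @seealso [runPermutationTest()]
#' @export
setClass("PermutationResult",
    representation(
        featureName = "character",
        observed = "integer",
        permuted = "integer",
        enrichment = "numeric",
        pEnrich = "numeric",
        pDeplete = "numeric",
        direction = "character",
        nSCE = "integer",
        degenerate = "logical",
        seed = "integer"
    )
)

setValidity("PermutationResult", function(object) {
    msg <- character()
    if (length(object@permuted) &&
        (any(object@permuted < 0L) || any(object@permuted > object@nSCE)))
        msg <- c(msg, "permuted overlaps must lie in [0, nSCE]")
    if (!is.na(object@enrichment) && object@enrichment < 0)
        msg <- c(msg, "enrichment must be >= 0")
    if (length(msg)) msg else TRUE
})

#' CohortComparison: HRD vs HRP deletion cohort report
#'
#' @slot perSample Data frame of per-sample metrics: sample, group, number
#'   of deletions, fraction fully inside a common fragile site (CFS), and
#'   among CFS deletions the fraction with junction microhomology at or
#'   above the threshold.
#' @slot groupSummary Data frame of per-group pooled percentages and
#'   box-plot statistics (mean, quartiles, 1.5 IQR whiskers) of the
#'   per-sample distributions.
#' @slot tests Data frame of two-sided rank-sum tests per metric with
#'   Benjamini-Hochberg adjusted p-values, plus pooled two-proportion
#'   tests.
#' @slot mhMin Microhomology threshold (bp) used for the MH metric.
#'
#' @seealso [cohortCompare()]
#' @export
setClass("CohortComparison",
    representation(
        perSample = "data.frame",
        groupSummary = "data.frame",
        tests = "data.frame",
        mhMin = "integer"
    )
)
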