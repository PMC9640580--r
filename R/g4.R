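#' Scan a sequence for G-quadruplex motifs
#'
#' Matches the canonical quadruplex pattern of four G-runs separated by
#' short loops, `G{3,} N{1,x} G{3,} N{1,x} G{3,} N{1,x} G{3,}`, where `N`
#' is any nucleotide and `x` is the maximum loop length (1-3, 1-7 or
#' 1-12 bp are the usual choices). Matching is leftmost and greedy with
#' non-overlapping successive matches (a new match starts after the end
#' of the previous one), so motif counts are monotone non-decreasing in
#' `x`. With `bothStrands = TRUE` the complementary pattern (C-runs) is
#' also scanned and the two coordinate lists are merged; G-quadruplexes
#' are strand-specific structures, so both orientations are reported by
#' default.
#'
#' @param sequence A character string, [Biostrings::DNAString] or
#'   single-entry [Biostrings::DNAStringSet]; alphabet `A/C/G/T/N`
#'   (case-insensitive).
#' @param loopMax Maximum loop length `x` in bp.
#' @param loopMin Minimum loop length (default 1).
#' @param runMin Minimum G-run length (default 3).
#' @param bothStrands Also scan for the reverse-strand pattern (C-runs)?
#' @return data.frame of motif intervals: `start`, `end` (0-based
#'   half-open, coordinates on the given sequence), `strand`
#'   (`+` for G-run matches, `-` for C-run matches).
#' @examples
#' scanG4("GGGAGGGTGGGCGGG", loopMax = 3)
#' @export
scanG4 <- function(sequence, loopMax = 7L, loopMin = 1L, runMin = 3L,
                   bothStrands = TRUE) {
    if (is(sequence, "DNAStringSet")) {
        stopifnot(length(sequence) == 1L)
        sequence <- as.character(sequence[[1L]])
    } else if (is(sequence, "DNAString")) {
        sequence <- as.character(sequence)
    }
    stopifnot(is.character(sequence), length(sequence) == 1L)
    if (loopMin < 1L) stop("loopMin must be >= 1")
    if (loopMax < loopMin) stop("loopMax must be >= loopMin")
    sequence <- toupper(sequence)
    if (grepl("[^ACGTN]", sequence))
        stop("sequence contains non-nucleotide symbols")
    scanOne <- function(base) {
        pat <- sprintf("%s{%d,}(?:[ACGTN]{%d,%d}%s{%d,}){3}",
                       base, runMin, loopMin, loopMax, base, runMin)
        m <- gregexpr(pat, sequence, perl = TRUE)[[1L]]
        if (m[1L] == -1L)
            return(data.frame(start = integer(0), end = integer(0)))
        data.frame(start = as.integer(m) - 1L,
                   end = as.integer(m) - 1L +
                       attr(m, "match.length"))
    }
    fw <- scanOne("G")
    fw$strand <- rep("+", nrow(fw))
    if (bothStrands) {
        rv <- scanOne("C")
        rv$strand <- rep("-", nrow(rv))
        fw <- rbind(fw, rv)
    }
    fw <- fw[order(fw$start, fw$end), , drop = FALSE]
    rownames(fw) <- NULL
    fw
}

#' @describeIn scanG4 Scan every chromosome of a genome (or DNAStringSet)
#'   and return a [GenomicRanges::GRanges] of motifs.
#' @param genome A [SyntheticGenome-class] with sequence, or a named
#'   [Biostrings::DNAStringSet].
#' @param ... Passed on to `scanG4`.
#' @export
scanG4Genome <- function(genome, ...) {
    seqs <- if (is(genome, "SyntheticGenome")) genomeSequence(genome)
            else genome
    if (is.null(seqs)) stop("genome carries no sequence")
    res <- lapply(names(seqs), function(chrom) {
        d <- scanG4(as.character(seqs[[chrom]]), ...)
        if (!nrow(d)) return(NULL)
        GRanges(chrom, IRanges(d$start + 1L, d$end),
                strand = d$strand)
    })
    out <- suppressWarnings(do.call(c, res[!vapply(res, is.null,
                                                   logical(1))]))
    if (is.null(out)) GRanges() else out
}
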