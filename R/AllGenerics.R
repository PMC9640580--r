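#' @rdname SyntheticGenome-class
#' @param x A `SyntheticGenome`.
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' @rdname SyntheticGenome-class
#' @export
setGeneric("gapRanges", function(x) standardGeneric("gapRanges"))

#' @rdname SyntheticGenome-class
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))

#' @rdname GapMask-class
#' @param mask A `GapMask`.
#' @param x Positions or ranges to map.
#' @param ... Further arguments.
#' @export
setGeneric("mapToMasked", function(mask, x, ...) standardGeneric("mapToMasked"))

#' @rdname GapMask-class
#' @export
setGeneric("mapFromMasked",
    function(mask, x, ...) standardGeneric("mapFromMasked"))

#' @describeIn SyntheticGenome-class Named vector of chromosome lengths (bp).
#' @export
setMethod("chromSizes", "SyntheticGenome", function(x) {
    seqlengths(x@seqinfo)
})

#' @describeIn SyntheticGenome-class GRanges of assembly gaps.
#' @export
setMethod("gapRanges", "SyntheticGenome", function(x) x@gaps)

#' @describeIn SyntheticGenome-class DNAStringSet of chromosome sequences,
#'   or NULL when the genome was simulated without sequence.
#' @export
setMethod("genomeSequence", "SyntheticGenome", function(x) x@sequence)

setMethod("show", "SyntheticGenome", function(object) {
    sl <- seqlengths(object@seqinfo)
    cat("SyntheticGenome with", length(sl), "chromosome(s),",
        sprintf("%.1f Mb total\n", sum(as.numeric(sl)) / 1e6))
    cat("  gaps:", length(object@gaps), "interval(s),",
        sprintf("%.2f Mb\n", sum(as.numeric(width(object@gaps))) / 1e6))
    cat("  sequence:", if (is.null(object@sequence)) "absent" else "present",
        "\n")
})

setMethod("show", "SCEParam", function(object) {
    cat("SCEParam: minMapq =", object@minMapq,
        "| minSupport =", object@minSupport,
        "| flipWindow =", object@flipWindow,
        "| segAlpha =", object@segAlpha, "\n")
})

setMethod("show", "PermParam", function(object) {
    cat("PermParam: nPerm =", object@nPerm,
        sprintf("| shift U[%g, %g] bp", object@shiftMin, object@shiftMax),
        sprintf("| sizeCutoff = %g bp\n", object@sizeCutoff))
})

setMethod("show", "PermutationResult", function(object) {
    cat("PermutationResult for feature '", object@featureName, "'\n",
        sep = "")
    cat("  SCEs tested:", object@nSCE,
        "| observed overlap:", object@observed, "\n")
    if (object@degenerate) {
        cat("  degenerate test (empty input or zero permuted median)\n")
        return(invisible(NULL))
    }
    cat("  median permuted overlap:",
        stats::median(object@permuted),
        sprintf("| enrichment = %.3f\n", object@enrichment))
    cat("  p(enrich) ", formatPermP(object@pEnrich, length(object@permuted)),
        " | p(deplete) ",
        formatPermP(object@pDeplete, length(object@permuted)),
        " | direction: ", object@direction, "\n", sep = "")
})

setMethod("show", "CohortComparison", function(object) {
    cat("CohortComparison (microhomology threshold >=", object@mhMin,
        "bp)\n")
    cat("Per-group summary:\n")
    print(object@groupSummary, row.names = FALSE)
    cat("Tests:\n")
    print(object@tests, row.names = FALSE)
})

setMethod("show", "GapMask", function(object) {
    cat("GapMask over", length(object@maskedLength), "chromosome(s);",
        sprintf("%.1f Mb non-gap space\n",
                sum(object@maskedLength) / 1e6))
})

# "p < 1/nPerm" style formatting used by show() and reports
formatPermP <- function(p, nPerm) {
    if (p <= 0) sprintf("< %g", 1 / nPerm) else sprintf("= %g", p)
}
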