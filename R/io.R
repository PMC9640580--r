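#' Read genomic intervals from BED or TSV
#'
#' Normalizes input intervals to the package's 0-based half-open
#' convention (returned as a standard [GenomicRanges::GRanges]). BED
#' input is parsed with \pkg{rtracklayer}; the `tsv` dialect expects
#' three whitespace-separated columns `chrom start end` (with or without
#' a header line) and converts from 1-based inclusive coordinates when
#' `oneBased = TRUE`.
#'
#' @param path File path.
#' @param dialect `"bed"` or `"tsv"`.
#' @param oneBased For `tsv` input: coordinates are 1-based inclusive
#'   and are converted (BED input is 0-based half-open by definition).
#' @param chromSizes Optional named vector; intervals beyond chromosome
#'   ends, or on unknown chromosomes, raise an error naming the line.
#' @return A sorted [GenomicRanges::GRanges].
#' @export
readIntervals <- function(path, dialect = c("bed", "tsv"),
                          oneBased = FALSE, chromSizes = NULL) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    if (dialect == "bed") {
        gr <- rtracklayer::import(path, format = "BED")
        hasHeader <- 0L
    } else {
        first <- utils::read.table(path, nrows = 1,
                                   stringsAsFactors = FALSE)
        hasHeader <- if (is.character(first[[2]])) 1L else 0L
        df <- utils::read.table(path, header = hasHeader == 1L,
                                stringsAsFactors = FALSE)
        names(df)[1:3] <- c("chrom", "start", "end")
        if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
            stop("malformed interval at line ",
                 which(!is.finite(df$start) |
                       !is.finite(df$end))[1] + hasHeader)
        if (oneBased) df$start <- df$start - 1
        bad <- which(df$start >= df$end)
        if (length(bad))
            stop("start >= end at line ", bad[1] + hasHeader)
        gr <- df0ToGRanges(df)
    }
    bad <- which(width(gr) < 1L)
    if (length(bad))
        stop("start >= end at line ", bad[1] + hasHeader)
    if (!is.null(chromSizes)) {
        unknown <- which(!as.character(seqnames(gr)) %in%
                         names(chromSizes))
        if (length(unknown))
            stop("unknown chromosome at line ",
                 unknown[1] + hasHeader)
        over <- which(end(gr) >
                      chromSizes[as.character(seqnames(gr))])
        if (length(over))
            stop("interval beyond chromosome end at line ",
                 over[1] + hasHeader)
        GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
        suppressWarnings(GenomeInfoDb::seqlengths(gr) <- chromSizes)
    }
    sort(gr)
}

#' Write intervals as BED
#'
#' Writes BED3, or BED6 when `name`/`score` columns are supplied or
#' present on the input. SCE events written with their library id as
#' name and the weaker flank support as score round-trip through
#' [readIntervals()].
#'
#' @param gr A [GenomicRanges::GRanges] (or 0-based data.frame
#'   `chrom`/`start`/`end`).
#' @param path Output path.
#' @param name,score Optional per-interval name and score vectors.
#' @return The path, invisibly.
#' @export
writeBED <- function(gr, path, name = NULL, score = NULL) {
    df <- if (is.data.frame(gr)) gr[c("chrom", "start", "end")]
          else grangesToDf0(gr)
    if (is.null(name) && !is.data.frame(gr) &&
        "libraryId" %in% names(mcols(gr)))
        name <- gr$libraryId
    if (is.null(score) && !is.data.frame(gr) &&
        all(c("leftSupport", "rightSupport") %in% names(mcols(gr))))
        score <- pmin(gr$leftSupport, gr$rightSupport)
    if (!is.null(name)) {
        df$name <- rep_len(name, nrow(df))
        df$score <- if (is.null(score)) rep_len(0L, nrow(df)) else score
        df$strand <- rep_len(".", nrow(df))
    }
    utils::write.table(format(df, scientific = FALSE, trim = TRUE),
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read/write a Strand-seq read table
#'
#' The TSV dialect has a header line `chrom pos strand mapq dup` with
#' 0-based positions, strand in `{W, C}` and `dup` as 0/1.
#'
#' @param path File path.
#' @return `readReadTable`: data.frame with columns `chrom`, `pos`,
#'   `strand`, `mapq`, `dup` (logical).
#' @export
readReadTable <- function(path) {
    df <- utils::read.table(path, header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "strand", "mapq", "dup")
    if (!all(need %in% names(df)))
        stop("read table must have header: ",
             paste(need, collapse = " "))
    bad <- which(!df$strand %in% c("W", "C"))
    if (length(bad))
        stop("unknown strand symbol at line ", bad[1] + 1L)
    df$dup <- as.logical(df$dup)
    df[need]
}

#' @rdname readReadTable
#' @param reads Read table to write.
#' @export
writeReadTable <- function(reads, path) {
    out <- reads[c("chrom", "pos", "strand", "mapq", "dup")]
    out$dup <- as.integer(out$dup)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Extract a Strand-seq read table from a BAM file
#'
#' One library per file, as in single-cell practice. The template strand
#' is taken from the read's mapped orientation: reads mapping to the
#' plus strand are Crick (`C`), minus-strand reads Watson (`W`).
#' Requires the \pkg{Rsamtools} package.
#'
#' @param path BAM path.
#' @return Read table data.frame (`chrom`, `pos` 0-based, `strand`,
#'   `mapq`, `dup`).
#' @export
readReadsFromBAM <- function(path) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
        stop("Rsamtools is required for BAM input")
    p <- Rsamtools::ScanBamParam(
        what = c("rname", "pos", "strand", "mapq", "flag"))
    b <- Rsamtools::scanBam(path, param = p)[[1L]]
    keep <- !is.na(b$pos)
    data.frame(
        chrom = as.character(b$rname)[keep],
        pos = b$pos[keep] - 1L,
        strand = ifelse(as.character(b$strand)[keep] == "+", "C", "W"),
        mapq = b$mapq[keep],
        dup = bitwAnd(b$flag[keep], 1024L) > 0L,
        stringsAsFactors = FALSE)
}

#' Write a SyntheticGenome to disk
#'
#' Emits `genome.fa` (when sequence is present), `chrom.sizes`
#' (two-column) and `gaps.bed` (BED3) into `dir`.
#'
#' @param genome A [SyntheticGenome-class].
#' @param dir Output directory (created if needed).
#' @return Named vector of the written paths, invisibly.
#' @export
writeGenome <- function(genome, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(chromSizes = file.path(dir, "chrom.sizes"),
               gaps = file.path(dir, "gaps.bed"))
    sl <- chromSizes(genome)
    utils::write.table(
        data.frame(names(sl), format(sl, scientific = FALSE,
                                     trim = TRUE)),
        paths["chromSizes"], sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    writeBED(gapRanges(genome), paths["gaps"])
    if (!is.null(genomeSequence(genome))) {
        paths["fasta"] <- file.path(dir, "genome.fa")
        writeXStringSet(genomeSequence(genome), paths["fasta"])
    }
    invisible(paths)
}
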