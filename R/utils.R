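# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards. seed = NULL uses (and
# advances) the current stream.
withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(eval.parent(substitute(expr)))
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("seed must be a single integer")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    eval.parent(substitute(expr))
}

# Derive a reproducible child seed from a parent seed and an index,
# keeping the result within the 32-bit integer range.
childSeed <- function(seed, i) {
    as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

checkProportion <- function(x, name, maxOpen = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
        (maxOpen && x >= 1) || (!maxOpen && x > 1))
        stop(name, " must be a proportion in [0, 1",
             if (maxOpen) ")" else "]")
    invisible(x)
}

# Longest common prefix length of two character strings, byte-wise,
# terminating at the first 'N' in either string.
commonPrefixLen <- function(a, b) {
    ra <- charToRaw(a)
    rb <- charToRaw(b)
    n <- min(length(ra), length(rb))
    if (n == 0L) return(0L)
    ra <- ra[seq_len(n)]
    rb <- rb[seq_len(n)]
    nRaw <- charToRaw("N")
    bad <- which(ra != rb | ra == nRaw | rb == nRaw)
    if (length(bad) == 0L) n else bad[1L] - 1L
}

reverseString <- function(x) {
    vapply(x, function(s)
        paste(rev(strsplit(s, NULL)[[1L]]), collapse = ""), character(1))
}

# 0-based half-open interval data.frame -> GRanges (1-based closed).
df0ToGRanges <- function(df, extraCols = character()) {
    gr <- GRanges(df$chrom,
                  IRanges(start = df$start + 1L, end = df$end))
    for (cc in extraCols) mcols(gr)[[cc]] <- df[[cc]]
    gr
}

# GRanges -> 0-based half-open data.frame.
grangesToDf0 <- function(gr) {
    data.frame(chrom = as.character(seqnames(gr)),
               start = start(gr) - 1L,
               end = end(gr),
               stringsAsFactors = FALSE)
}

isAutosomeName <- function(x) {
    grepl("^(chr)?[0-9]+$", x)
}
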