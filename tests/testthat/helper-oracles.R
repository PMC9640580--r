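# Brute-force reference implementations used as independent oracles.
# These deliberately use the most literal algorithm available (per-base
# marking, direct summation, explicit backtracking) rather than the
# package's data structures.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
})

# Number of query intervals (0-based half-open) overlapping any subject
# interval by >= 1 bp, by marking every covered base.
oracleOverlapCount <- function(qs, qe, ss, se, spaceMax) {
    covered <- logical(spaceMax)
    for (i in seq_along(ss)) {
        if (se[i] > ss[i]) covered[(ss[i] + 1):se[i]] <- TRUE
    }
    hits <- 0L
    for (i in seq_along(qs)) {
        if (qe[i] > qs[i] && any(covered[(qs[i] + 1):qe[i]]))
            hits <- hits + 1L
    }
    hits
}

# Per-base stacking depth of a set of 0-based half-open intervals.
oracleDepth <- function(s, e, spaceMax) {
    depth <- integer(spaceMax)
    for (i in seq_along(s)) {
        if (e[i] > s[i])
            depth[(s[i] + 1):e[i]] <- depth[(s[i] + 1):e[i]] + 1L
    }
    depth
}

# Binomial upper tail P(X >= k) by direct summation of the mass.
oracleBinomTail <- function(k, N, p) {
    if (k <= 0) return(1)
    sum(vapply(k:N, function(j)
        choose(N, j) * p^j * (1 - p)^(N - j), double(1)))
}

# Quadruplex motif count by explicit backtracking that mirrors
# leftmost-greedy regex semantics: at each start position, G-runs
# prefer maximal length, loops prefer maximal length, first success
# wins; scanning resumes after the match end.
oracleG4Count <- function(seq, loopMax, loopMin = 1L, runMin = 3L,
                          base = "G") {
    chars <- strsplit(seq, NULL)[[1L]]
    n <- length(chars)
    runAt <- function(i) {
        j <- i
        while (j <= n && chars[j] == base) j <- j + 1L
        j - i
    }
    tryFrom <- function(i, stage) {
        if (stage %% 2L == 1L) {           # G-run
            maxLen <- runAt(i)
            if (maxLen < runMin) return(-1L)
            if (stage == 7L) return(i + maxLen)   # final run: greedy
            for (L in seq(maxLen, runMin)) {
                r <- tryFrom(i + L, stage + 1L)
                if (r > 0L) return(r)
            }
            -1L
        } else {                           # loop (any nucleotide)
            maxLen <- min(loopMax, n - i + 1L)
            if (maxLen < loopMin) return(-1L)
            for (L in seq(maxLen, loopMin)) {
                r <- tryFrom(i + L, stage + 1L)
                if (r > 0L) return(r)
            }
            -1L
        }
    }
    count <- 0L
    i <- 1L
    while (i <= n - 4L * runMin - 3L * loopMin + 1L) {
        r <- tryFrom(i, 1L)
        if (r > 0L) {
            count <- count + 1L
            i <- r
        } else {
            i <- i + 1L
        }
    }
    count
}

# Junction microhomology by explicit character-by-character comparison
# on split vectors.
oracleMH <- function(seqChars, start0, end0, probe = 50L) {
    len <- end0 - start0
    fwd <- 0L
    while (fwd < min(len, probe) && end0 + fwd < length(seqChars)) {
        a <- seqChars[start0 + fwd + 1L]
        b <- seqChars[end0 + fwd + 1L]
        if (a != b || a == "N" || b == "N") break
        fwd <- fwd + 1L
    }
    rev <- 0L
    while (rev < min(len, probe) && start0 - rev >= 1L) {
        a <- seqChars[end0 - rev]
        b <- seqChars[start0 - rev]
        if (a != b || a == "N" || b == "N") break
        rev <- rev + 1L
    }
    min(fwd + rev, len)
}

# Random G-enriched nucleotide string (G4 motifs are vanishingly rare in
# uniform-random sequence).
randomGRichSeq <- function(n, pG = 0.4) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - pG) / 3, (1 - pG) / 3, pG,
                          (1 - pG) / 3)), collapse = "")
}

makeReads <- function(pos, strand, chrom = "chr1", mapq = 60L,
                      dup = FALSE) {
    data.frame(chrom = chrom, pos = pos, strand = strand,
               mapq = mapq, dup = dup, stringsAsFactors = FALSE)
}
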