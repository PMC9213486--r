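# Independent oracles used by the test suite.
#
# bruteGlobal / bruteLocal enumerate every possible alignment path
# explicitly (no dynamic-programming recurrences or memoisation), scoring
# affine gaps as gap_open + k * gap_extend per gap of length k.  They are
# exponential-time and only usable for short sequences, which is the point:
# they are independent of the package's alignment machinery.

.oracleScore <- function(x, y, match, mismatch) {
    if (x == y) match else mismatch
}

bruteGlobal <- function(a, b, match = 1, mismatch = -2,
                        gap_open = 5, gap_extend = 2) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    m <- length(av); n <- length(bv)
    best <- -Inf
    rec <- function(i, j, last, sc) {
        if (i > m && j > n) {
            if (sc > best) best <<- sc
            return(invisible(NULL))
        }
        if (i <= m && j <= n)
            rec(i + 1, j + 1, "D", sc + .oracleScore(av[i], bv[j],
                                                     match, mismatch))
        if (i <= m)   # gap in b, consume a[i]
            rec(i + 1, j, "U", sc - (if (last == "U") gap_extend
                                     else gap_open + gap_extend))
        if (j <= n)   # gap in a, consume b[j]
            rec(i, j + 1, "L", sc - (if (last == "L") gap_extend
                                     else gap_open + gap_extend))
        invisible(NULL)
    }
    rec(1, 1, "S", 0)
    best
}

bruteLocal <- function(a, b, match = 1, mismatch = -2,
                       gap_open = 5, gap_extend = 2) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    m <- length(av); n <- length(bv)
    best <- 0   # empty alignment always available
    rec <- function(i, j, last, sc) {
        # sc is the running score of a path whose first column aligned
        # residues; record whenever the path ends on an aligned column
        # (trailing gaps never improve a local score).
        if (last == "D" && sc > best) best <<- sc
        if (i > m || j > n) return(invisible(NULL))
        rec(i + 1, j + 1, "D", sc + .oracleScore(av[i], bv[j],
                                                 match, mismatch))
        if (i <= m)
            rec(i + 1, j, "U", sc - (if (last == "U") gap_extend
                                     else gap_open + gap_extend))
        if (j <= n)
            rec(i, j + 1, "L", sc - (if (last == "L") gap_extend
                                     else gap_open + gap_extend))
        invisible(NULL)
    }
    for (i0 in seq_len(m)) for (j0 in seq_len(n))
        rec(i0 + 1, j0 + 1, "D", .oracleScore(av[i0], bv[j0],
                                              match, mismatch))
    best
}

# Exhaustive confusion-matrix oracle.
bruteConfusion <- function(taxa, called, truth) {
    tp <- fp <- tn <- fn <- 0
    for (t in taxa) {
        p <- t %in% called
        y <- t %in% truth
        if (p && y) tp <- tp + 1
        if (p && !y) fp <- fp + 1
        if (!p && y) fn <- fn + 1
        if (!p && !y) tn <- tn + 1
    }
    c(tp = tp, fp = fp, tn = tn, fn = fn)
}

randomSeq <- function(len, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

blastAvailable <- function() all(nzchar(Sys.which(c(
    "makeblastdb", "blastn", "blastp"))))
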