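## Pairwise alignment surface: Needleman-Wunsch / Smith-Waterman with affine
## gaps (backed by Biostrings dynamic programming) plus Karlin-Altschul
## e-values and percent identity.

.NUC_ALPHABET <- c("A", "C", "G", "T")
.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.checkAlphabet <- function(x, kind) {
    chars <- unique(strsplit(toupper(x), "")[[1]])
    ok <- if (kind == "nucleotide") .NUC_ALPHABET else .AA_ALPHABET
    bad <- setdiff(chars, ok)
    if (length(bad))
        stop("illegal residue(s) for ", kind, " alignment: ",
             paste(bad, collapse = ", "))
    invisible(x)
}

.substitutionMatrix <- function(scheme) {
    if (scheme@kind == "nucleotide") {
        Biostrings::nucleotideSubstitutionMatrix(
            match = scheme@match, mismatch = scheme@mismatch, baseOnly = TRUE)
    } else {
        ## pulls e.g. BLOSUM62 from Biostrings' bundled matrices
        getdata <- new.env()
        utils::data(list = scheme@matrix, package = "Biostrings",
                    envir = getdata)
        get(scheme@matrix, envir = getdata)
    }
}

.pairAlign <- function(a, b, scheme, type, query_id, subject_id) {
    a <- toupper(a); b <- toupper(b)
    if (!nchar(a) || !nchar(b))
        stop("sequences must be non-empty")
    .checkAlphabet(a, scheme@kind)
    .checkAlphabet(b, scheme@kind)
    maker <- if (scheme@kind == "nucleotide") Biostrings::DNAString
        else Biostrings::AAString
    pa <- Biostrings::pairwiseAlignment(
        maker(a), maker(b), type = type,
        substitutionMatrix = .substitutionMatrix(scheme),
        gapOpening = scheme@gap_open, gapExtension = scheme@gap_extend)
    aq <- as.character(Biostrings::alignedPattern(pa))
    as_ <- as.character(Biostrings::alignedSubject(pa))
    cq <- strsplit(aq, "")[[1]]
    cs <- strsplit(as_, "")[[1]]
    gap <- cq == "-" | cs == "-"
    matches <- sum(!gap & cq == cs)
    mismatches <- sum(!gap & cq != cs)
    len <- length(cq)
    sc <- Biostrings::score(pa)
    if (type == "local" && sc <= 0) {
        ## empty local alignment
        return(new("PairwiseHit", query_id = query_id,
                   subject_id = subject_id, type = type, score = 0,
                   matches = 0L, mismatches = 0L, gap_columns = 0L,
                   identity_pct = 0, evalue = NA_real_,
                   query_start = 0L, query_end = 0L,
                   subject_start = 0L, subject_end = 0L,
                   aligned_query = "", aligned_subject = ""))
    }
    ev <- if (type == "local")
        alignmentEvalue(sc, nchar(a), nchar(b), scheme@lambda, scheme@K)
    else NA_real_
    qs <- if (type == "local")
        Biostrings::start(Biostrings::pattern(pa)) - 1L else 0L
    qe <- if (type == "local")
        Biostrings::end(Biostrings::pattern(pa)) else nchar(a)
    ss <- if (type == "local")
        Biostrings::start(Biostrings::subject(pa)) - 1L else 0L
    se <- if (type == "local")
        Biostrings::end(Biostrings::subject(pa)) else nchar(b)
    new("PairwiseHit", query_id = query_id, subject_id = subject_id,
        type = type, score = sc, matches = as.integer(matches),
        mismatches = as.integer(mismatches),
        gap_columns = as.integer(sum(gap)),
        identity_pct = if (len > 0) 100 * matches / len else 0,
        evalue = ev,
        query_start = as.integer(qs), query_end = as.integer(qe),
        subject_start = as.integer(ss), subject_end = as.integer(se),
        aligned_query = aq, aligned_subject = as_)
}

#' Optimal global (Needleman-Wunsch) alignment with affine gaps
#'
#' A gap of length k costs `gap_open + k * gap_extend`.
#'
#' @param a,b sequences (character) over the scheme's alphabet.
#' @param scheme A [ScoringScheme-class].
#' @param query_id,subject_id identifiers recorded in the result.
#' @return A [PairwiseHit-class].
#' @examples
#' globalAlign("ACGT", "ACGT")
#' @export
globalAlign <- function(a, b, scheme = scoringScheme("nucleotide"),
                        query_id = "query", subject_id = "subject") {
    .pairAlign(a, b, scheme, "global", query_id, subject_id)
}

#' Optimal local (Smith-Waterman) alignment with affine gaps
#'
#' The empty alignment (score 0) is allowed when no positive-scoring local
#' alignment exists.
#'
#' @inheritParams globalAlign
#' @return A [PairwiseHit-class].
#' @examples
#' localAlign("CCCACGTCCC", "ACGT")
#' @export
localAlign <- function(a, b, scheme = scoringScheme("nucleotide"),
                       query_id = "query", subject_id = "subject") {
    .pairAlign(a, b, scheme, "local", query_id, subject_id)
}

#' Karlin-Altschul e-value of an alignment score
#'
#' E = K * m * n * exp(-lambda * score).
#'
#' @param score alignment score.
#' @param m,n query and database lengths (> 0).
#' @param lambda,K Karlin-Altschul parameters (> 0).
#' @return Expected number of chance alignments at or above `score`.
#' @examples
#' alignmentEvalue(30, 500, 2e5, 1.33, 0.621)
#' @export
alignmentEvalue <- function(score, m, n, lambda, K) {
    if (lambda <= 0 || K <= 0)
        stop("lambda and K must be > 0")
    if (m <= 0 || n <= 0)
        stop("m and n must be > 0")
    K * m * n * exp(-lambda * score)
}

#' Percent identity of an alignment
#'
#' @param hit A [PairwiseHit-class].
#' @param mode "all_columns" (matches / alignment length; the BLAST
#'   convention and the default) or "ungapped_columns"
#'   (matches / (matches + mismatches)).
#' @return Percent identity with attribute `mode` recording the convention.
#' @export
percentIdentity <- function(hit, mode = c("all_columns",
                                          "ungapped_columns")) {
    mode <- match.arg(mode)
    len <- hit@matches + hit@mismatches + hit@gap_columns
    if (mode == "all_columns") {
        if (len == 0L) stop("undefined: zero-length alignment")
        out <- 100 * hit@matches / len
    } else {
        if (hit@matches + hit@mismatches == 0L)
            stop("undefined: no aligned residue columns")
        out <- 100 * hit@matches / (hit@matches + hit@mismatches)
    }
    structure(out, mode = mode)
}
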