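## Genome/proteome relatedness: fragment-based ANI, reciprocal-best-hit AAI,
## tetranucleotide signature correlation, species calls, MAG quality filter
## and dereplication.

.fragmentContigs <- function(contigs, fragment_bp = 1020L, min_tail = 100L) {
    frags <- list()
    for (i in seq_along(contigs)) {
        w <- Biostrings::width(contigs[i])
        if (w < min_tail) next
        starts <- seq(1L, w, by = fragment_bp)
        ends <- pmin(starts + fragment_bp - 1L, w)
        keep <- (ends - starts + 1L) >= min_tail
        if (!any(keep)) next
        v <- Biostrings::Views(contigs[[i]], start = starts[keep],
                               end = ends[keep])
        frags[[i]] <- Biostrings::DNAStringSet(v)
    }
    out <- do.call(c, frags[!vapply(frags, is.null, logical(1))])
    if (is.null(out)) out <- Biostrings::DNAStringSet()
    if (length(out)) names(out) <- paste0("frag", seq_along(out))
    out
}

.aniOneWay <- function(a_contigs, db, fragment_bp, min_frag_identity,
                       min_frag_coverage) {
    frags <- .fragmentContigs(a_contigs, fragment_bp)
    if (!length(frags))
        return(list(ani = NA_real_, n = 0L))
    hits <- .bestHits(.blastTable(frags, db, "blastn", evalue = 1e-5))
    if (nrow(hits) == 0L)
        return(list(ani = NA_real_, n = 0L))
    fw <- Biostrings::width(frags)[match(hits$qseqid, names(frags))]
    ok <- hits$pident >= min_frag_identity &
        hits$length >= (min_frag_coverage / 100) * fw
    if (!any(ok))
        return(list(ani = NA_real_, n = 0L))
    list(ani = mean(hits$pident[ok]), n = sum(ok))
}

#' Fragment-based average nucleotide identity (ANI)
#'
#' The query genome is cut into consecutive `fragment_bp` fragments (tails
#' under 100 bp dropped) which are searched against the subject genome on
#' both strands; fragments whose best hit reaches `min_frag_identity`
#' percent identity over at least `min_frag_coverage` percent of their
#' length contribute, and ANI is the mean identity of contributing
#' fragments.  The value is symmetrised as the mean of the two directions.
#' Fragment length and thresholds follow the JSpecies convention.
#'
#' @param a,b [GenomeRecord-class] objects with non-empty contigs.
#' @param fragment_bp fragment length, bp (default 1020).
#' @param min_frag_identity minimum fragment identity, percent (default 30).
#' @param min_frag_coverage minimum fragment alignment coverage, percent
#'   (default 70).
#' @return list with `ani` (percent, NA when undefined), `fragments_used`
#'   (per direction) and `reason` when undefined.
#' @export
ani <- function(a, b, fragment_bp = 1020L, min_frag_identity = 30,
                min_frag_coverage = 70) {
    if (!length(a@contigs) || !length(b@contigs))
        stop("both genomes must have contigs")
    db_b <- .makeBlastDb(b@contigs, "nucl")
    db_a <- .makeBlastDb(a@contigs, "nucl")
    on.exit(unlink(c(dirname(db_a), dirname(db_b)), recursive = TRUE))
    ab <- .aniOneWay(a@contigs, db_b, fragment_bp, min_frag_identity,
                     min_frag_coverage)
    ba <- .aniOneWay(b@contigs, db_a, fragment_bp, min_frag_identity,
                     min_frag_coverage)
    vals <- c(ab$ani, ba$ani)
    if (all(is.na(vals)))
        return(list(ani = NA_real_, fragments_used = c(ab$n, ba$n),
                    reason = "no fragment passed the identity/coverage thresholds"))
    list(ani = mean(vals, na.rm = TRUE), fragments_used = c(ab$n, ba$n),
         reason = NA_character_)
}

.bestProteinHits <- function(queries, db, min_identity, max_evalue,
                             min_coverage) {
    hits <- .bestHits(.blastTable(queries, db, "blastp",
                                  evalue = max_evalue))
    if (nrow(hits) == 0L)
        return(hits)
    qw <- Biostrings::width(queries)[match(hits$qseqid, names(queries))]
    hits[hits$pident >= min_identity & hits$evalue <= max_evalue &
             hits$length >= (min_coverage / 100) * qw, , drop = FALSE]
}

#' Reciprocal-best-hit average amino acid identity (AAI)
#'
#' Best hits are computed in both directions by protein database search
#' subject to identity, e-value and query-coverage thresholds; mutually best
#' pairs form the RBH set and AAI is the mean identity over RBH pairs (the
#' two directional identities of each pair are averaged, which makes
#' `aai(a, b)` exactly symmetric).
#'
#' @param a,b [GenomeRecord-class] objects with non-empty proteomes, or
#'   [Biostrings::AAStringSet] proteomes.
#' @param min_identity,max_evalue,min_coverage hit thresholds (defaults
#'   20%, 1e-5, 50%).
#' @return list with `aai` (percent, NA when undefined), `rbh_count` and
#'   `reason` when undefined.
#' @export
aai <- function(a, b, min_identity = 20, max_evalue = 1e-5,
                min_coverage = 50) {
    pa <- if (is(a, "GenomeRecord")) a@proteome else Biostrings::AAStringSet(a)
    pb <- if (is(b, "GenomeRecord")) b@proteome else Biostrings::AAStringSet(b)
    if (!length(pa) || !length(pb))
        stop("both proteomes must be non-empty")
    if (is.null(names(pa))) names(pa) <- paste0("a", seq_along(pa))
    if (is.null(names(pb))) names(pb) <- paste0("b", seq_along(pb))
    db_b <- .makeBlastDb(pb, "prot")
    db_a <- .makeBlastDb(pa, "prot")
    on.exit(unlink(c(dirname(db_a), dirname(db_b)), recursive = TRUE))
    fwd <- .bestProteinHits(pa, db_b, min_identity, max_evalue, min_coverage)
    rev <- .bestProteinHits(pb, db_a, min_identity, max_evalue, min_coverage)
    if (nrow(fwd) == 0L || nrow(rev) == 0L)
        return(list(aai = NA_real_, rbh_count = 0L,
                    reason = "empty reciprocal-best-hit set"))
    key_fwd <- paste(fwd$qseqid, fwd$sseqid)
    key_rev <- paste(rev$sseqid, rev$qseqid)
    rbh <- fwd[key_fwd %in% key_rev, , drop = FALSE]
    if (nrow(rbh) == 0L)
        return(list(aai = NA_real_, rbh_count = 0L,
                    reason = "empty reciprocal-best-hit set"))
    rev_id <- rev$pident[match(paste(rbh$qseqid, rbh$sseqid), key_rev)]
    list(aai = mean((rbh$pident + rev_id) / 2), rbh_count = nrow(rbh),
         reason = NA_character_)
}

## Both-strand k-mer counts over all contigs.
.kmerCounts <- function(contigs, k) {
    fwd <- colSums(Biostrings::oligonucleotideFrequency(contigs, k))
    rev <- colSums(Biostrings::oligonucleotideFrequency(
        Biostrings::reverseComplement(contigs), k))
    fwd + rev
}

#' Tetranucleotide usage z-score signature
#'
#' Counts all 256 tetranucleotides on both strands and standardises each
#' count against its maximal-order Markov (trinucleotide) expectation:
#' E(n1n2n3n4) = n(n1n2n3) n(n2n3n4) / n(n2n3), with the Teeling variance
#' approximation.  Windows containing non-ACGT bases are not counted.
#'
#' @param genome A [GenomeRecord-class] or [Biostrings::DNAStringSet].
#' @return Named numeric vector of 256 z-scores.
#' @export
tetraSignature <- function(genome) {
    contigs <- if (is(genome, "GenomeRecord")) genome@contigs
        else Biostrings::DNAStringSet(genome)
    if (sum(Biostrings::width(contigs)) < 10000)
        warning("tetranucleotide signature on < 10 kb of sequence is noisy")
    n4 <- .kmerCounts(contigs, 4L)
    n3 <- .kmerCounts(contigs, 3L)
    n2 <- .kmerCounts(contigs, 2L)
    tets <- names(n4)
    left <- substr(tets, 1, 3)
    right <- substr(tets, 2, 4)
    mid <- substr(tets, 2, 3)
    E <- n3[left] * n3[right] / n2[mid]
    v <- E * ((n2[mid] - n3[left]) * (n2[mid] - n3[right])) / n2[mid]^2
    z <- ifelse(is.finite(E) & v > 0, (n4 - E) / sqrt(v), 0)
    stats::setNames(as.numeric(z), tets)
}

#' Pearson correlation of two tetranucleotide signatures
#'
#' @param a,b [GenomeRecord-class] objects, DNAStringSets, or precomputed
#'   signatures from [tetraSignature()].
#' @return Pearson correlation coefficient in \[-1, 1\].
#' @export
tetraCorrelation <- function(a, b) {
    sig <- function(x) if (is.numeric(x)) x else tetraSignature(x)
    stats::cor(sig(a), sig(b))
}

#' Species-delineation decision from relatedness indices
#'
#' Same species iff ANI >= `ani_cutoff` when ANI is defined; otherwise the
#' AAI rule (>= `aai_cutoff`) decides.  Cut-offs default to the recommended
#' 95% ANI and ~70% AAI species boundaries.
#'
#' @param ani_pct,aai_pct percent identities (NA when undefined).
#' @param ani_cutoff,aai_cutoff inclusive cut-offs (defaults 95, 70).
#' @return list echoing the inputs with logicals `ani_same`, `aai_same`,
#'   the combined `same_species`, and `callable`.
#' @examples
#' sameSpecies(ani_pct = 99.99)$same_species   # TRUE
#' sameSpecies(ani_pct = 82.6)$same_species    # FALSE
#' @export
sameSpecies <- function(ani_pct = NA_real_, aai_pct = NA_real_,
                        ani_cutoff = 95, aai_cutoff = 70) {
    if (is.na(ani_pct) && is.na(aai_pct))
        return(list(ani = ani_pct, aai = aai_pct, ani_same = NA,
                    aai_same = NA, same_species = NA, callable = FALSE))
    ani_same <- if (is.na(ani_pct)) NA else ani_pct >= ani_cutoff
    aai_same <- if (is.na(aai_pct)) NA else aai_pct >= aai_cutoff
    list(ani = ani_pct, aai = aai_pct, ani_same = ani_same,
         aai_same = aai_same,
         same_species = if (!is.na(ani_pct)) ani_same else aai_same,
         callable = TRUE)
}

#' Quality-filter MAG records
#'
#' Retains records with completeness strictly above `min_completeness` and
#' contamination strictly below `max_contamination`.  Records with missing
#' metadata are excluded with a reason.
#'
#' @param records list of [GenomeRecord-class] objects, or a data.frame with
#'   columns `id`, `completeness`, `contamination`.
#' @param min_completeness,max_contamination percent thresholds (defaults
#'   70, 5; strict inequalities).
#' @return The retained subset (same type as the input); attribute
#'   `excluded` is a data.frame of dropped ids with reasons.
#' @examples
#' tab <- data.frame(id = c("m1", "m2"), completeness = c(86.9, 70.0),
#'                   contamination = c(4.8, 1.0))
#' qualityFilter(tab)$id   # "m1"
#' @export
qualityFilter <- function(records, min_completeness = 70,
                          max_contamination = 5) {
    if (is.data.frame(records)) {
        comp <- records$completeness
        cont <- records$contamination
        ids <- records$id
    } else {
        comp <- vapply(records, function(r) r@completeness, numeric(1))
        cont <- vapply(records, function(r) r@contamination, numeric(1))
        ids <- vapply(records, function(r) r@id, character(1))
    }
    reason <- rep(NA_character_, length(ids))
    reason[is.na(comp) | is.na(cont)] <- "missing quality metadata"
    miss <- is.na(comp) | is.na(cont)
    fail <- !miss & !(comp > min_completeness & cont < max_contamination)
    reason[fail] <- "below quality thresholds"
    keep <- !miss & !fail
    out <- if (is.data.frame(records)) records[keep, , drop = FALSE]
        else records[keep]
    attr(out, "excluded") <- data.frame(id = ids[!keep],
                                        reason = reason[!keep],
                                        stringsAsFactors = FALSE)
    out
}

#' Dereplicate genomes at an ANI threshold
#'
#' Genomes are clustered by single linkage over pairs with ANI at or above
#' `ani_threshold` (undefined pairwise ANI counts as below threshold); from
#' each cluster the highest-scoring record is retained, with score =
#' completeness - 5 * contamination and deterministic alphabetical
#' tie-break.
#'
#' @param records list of [GenomeRecord-class] objects.
#' @param ani_threshold clustering threshold, percent (default 95).
#' @param ani_matrix optional precomputed symmetric matrix of pairwise ANI
#'   percentages (NA = undefined); computed with [ani()] when missing.
#' @return list with `representatives` (retained records), `clusters`
#'   (integer membership vector named by id) and `scores`.
#' @export
dereplicate <- function(records, ani_threshold = 95, ani_matrix = NULL) {
    stopifnot(length(records) >= 1L)
    ids <- vapply(records, function(r) r@id, character(1))
    n <- length(records)
    if (is.null(ani_matrix)) {
        ani_matrix <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
        if (n > 1L) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
            v <- ani(records[[i]], records[[j]])$ani
            ani_matrix[i, j] <- ani_matrix[j, i] <- v
        }
    }
    adj <- !is.na(ani_matrix) & ani_matrix >= ani_threshold
    comp <- local({
        parent <- seq_len(n)
        find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
        if (n > 1L) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
            if (adj[i, j]) {
                ri <- find(i); rj <- find(j)
                if (ri != rj) parent[rj] <- ri
            }
        }
        vapply(seq_len(n), find, integer(1))
    })
    score <- vapply(records, function(r) {
        cs <- if (is.na(r@completeness)) 0 else r@completeness
        ct <- if (is.na(r@contamination)) 0 else r@contamination
        cs - 5 * ct
    }, numeric(1))
    reps <- integer(0)
    for (cl in unique(comp)) {
        members <- which(comp == cl)
        members <- members[order(-score[members], ids[members])]
        reps <- c(reps, members[1])
    }
    reps <- sort(reps)
    list(representatives = records[reps],
         clusters = stats::setNames(match(comp, unique(comp)), ids),
         scores = stats::setNames(score, ids))
}
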