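## SDIMO / pMMO marker screening, group assignment, and fragment-recruitment
## abundance of MAGs in metagenomes.

#' Screen a proteome for SDIMO and membrane-bound monooxygenase markers
#'
#' Each query protein is searched against the reference panel; the best hit
#' passing the identity, e-value and query-coverage thresholds is reported.
#' Queries with no passing hit are omitted.
#'
#' @param proteome [Biostrings::AAStringSet] (or [GenomeRecord-class]).
#' @param panel A [MarkerPanel-class].
#' @param min_identity,max_evalue,min_coverage thresholds (defaults 30%,
#'   1e-5, 50%).
#' @return data.frame with columns `query_id`, `best_reference`, `family`,
#'   `group`, `identity`, `evalue`, `coverage` — one row per passing query.
#' @export
findMarkers <- function(proteome, panel, min_identity = 30,
                        max_evalue = 1e-5, min_coverage = 50) {
    if (is(proteome, "GenomeRecord"))
        proteome <- proteome@proteome
    proteome <- Biostrings::AAStringSet(proteome)
    empty <- data.frame(query_id = character(), best_reference = character(),
                        family = character(), group = character(),
                        identity = numeric(), evalue = numeric(),
                        coverage = numeric(), stringsAsFactors = FALSE)
    if (!length(proteome))
        return(empty)
    if (!nrow(panel@manifest))
        stop("marker panel is empty")
    if (is.null(names(proteome)))
        names(proteome) <- paste0("prot", seq_along(proteome))
    db <- .makeBlastDb(panel@sequences, "prot")
    on.exit(unlink(dirname(db), recursive = TRUE))
    hits <- .bestHits(.blastTable(proteome, db, "blastp",
                                  evalue = max_evalue))
    if (nrow(hits) == 0L)
        return(empty)
    qw <- Biostrings::width(proteome)[match(hits$qseqid, names(proteome))]
    cov <- 100 * hits$length / qw
    keep <- hits$pident >= min_identity & hits$evalue <= max_evalue &
        cov >= min_coverage
    hits <- hits[keep, , drop = FALSE]
    cov <- cov[keep]
    if (nrow(hits) == 0L)
        return(empty)
    m <- match(hits$sseqid, panel@manifest$id)
    data.frame(query_id = hits$qseqid, best_reference = hits$sseqid,
               family = panel@manifest$family[m],
               group = panel@manifest$group[m],
               identity = hits$pident, evalue = hits$evalue,
               coverage = cov, stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign SDIMO groups to marker candidates
#'
#' Nearest-reference surrogate for phylogenetic placement: a candidate takes
#' the group of its best reference when its identity reaches the assignment
#' floor, otherwise "undefined" — mirroring alpha-subunit sequences that do
#' not cluster within a known SDIMO group.
#'
#' @param candidates data.frame from [findMarkers()].
#' @param assignment_floor minimum identity (percent) for a confident group
#'   assignment (default 40).
#' @return The input with an `assigned_group` column ("undefined" below the
#'   floor).
#' @export
assignGroup <- function(candidates, assignment_floor = 40) {
    candidates$assigned_group <- ifelse(
        candidates$identity >= assignment_floor,
        candidates$group, "undefined")
    candidates
}

#' Fragment-recruitment abundance of a MAG in a metagenome
#'
#' A query sequence (read or scaffold) is recruited iff its best hit against
#' the MAG, on either strand, has identity strictly above `min_identity`
#' percent and e-value strictly below `max_evalue`.  Abundance is the
#' percentage of queries recruited.  Queries shorter than 100 bp are skipped
#' (e-values unreliable) and counted.
#'
#' @param queries [Biostrings::DNAStringSet] of reads or scaffolds.
#' @param mag A [GenomeRecord-class] with non-empty contigs.
#' @param min_identity,max_evalue recruitment thresholds (defaults 95%,
#'   1e-5; both strict).
#' @return list with `mag_id`, `total_queries`, `recruited`,
#'   `abundance_pct`, `skipped_short`.
#' @export
recruitAbundance <- function(queries, mag, min_identity = 95,
                             max_evalue = 1e-5) {
    queries <- Biostrings::DNAStringSet(queries)
    if (!length(queries))
        stop("queries must be non-empty")
    if (!length(mag@contigs))
        stop("MAG has no contigs")
    if (is.null(names(queries)))
        names(queries) <- paste0("read", seq_along(queries))
    short <- Biostrings::width(queries) < 100L
    use <- queries[!short]
    recruited <- 0L
    if (length(use)) {
        db <- .makeBlastDb(mag@contigs, "nucl")
        on.exit(unlink(dirname(db), recursive = TRUE))
        hits <- .bestHits(.blastTable(use, db, "blastn",
                                      evalue = max_evalue))
        if (nrow(hits))
            recruited <- sum(hits$pident > min_identity &
                                 hits$evalue < max_evalue)
    }
    total <- length(use)
    list(mag_id = mag@id, total_queries = total,
         recruited = as.integer(recruited),
         abundance_pct = if (total > 0) 100 * recruited / total else NaN,
         skipped_short = sum(short))
}

#' Marker presence/absence and abundance report across MAGs
#'
#' One row per MAG: logical presence of each SDIMO group (I-VI, pMMO) from
#' the marker screen of its proteome, plus fragment-recruitment abundance in
#' each supplied metagenome.
#'
#' @param mags list of [GenomeRecord-class] objects.
#' @param panel A [MarkerPanel-class].
#' @param metagenomes named list of [Biostrings::DNAStringSet] query sets
#'   (reads or scaffolds); may be empty.
#' @param assignment_floor passed to [assignGroup()].
#' @param ... passed to [findMarkers()].
#' @return data.frame with columns `mag_id`, `present_<group>` logicals and
#'   `abundance_<metagenome>` percentages.
#' @export
screenReport <- function(mags, panel, metagenomes = list(),
                         assignment_floor = 40, ...) {
    groups <- .VALID_GROUPS
    rows <- lapply(mags, function(mag) {
        cand <- assignGroup(findMarkers(mag, panel, ...), assignment_floor)
        present <- groups %in% cand$assigned_group
        row <- data.frame(mag_id = mag@id, stringsAsFactors = FALSE)
        for (g in seq_along(groups))
            row[[paste0("present_", groups[g])]] <- present[g]
        for (mg in names(metagenomes))
            row[[paste0("abundance_", mg)]] <-
                recruitAbundance(metagenomes[[mg]], mag)$abundance_pct
        row
    })
    do.call(rbind, rows)
}
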