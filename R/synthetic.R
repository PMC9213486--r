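## Synthetic sequence generators: random genomes/proteomes, substitution
## mutants, read sampling, and a synthetic SDIMO marker panel.  These stand
## in for deposited sequence data so every stage of the pipeline is testable
## without downloads; all synthetic objects are labelled as such.

#' Random nucleotide genome
#'
#' @param length_bp genome length in bp.
#' @param gc GC content, fraction.
#' @param seed integer seed.
#' @param id contig name.
#' @return [Biostrings::DNAStringSet] with one contig.
#' @export
randomGenome <- function(length_bp, gc = 0.5, seed = 1L, id = "contig1") {
    set.seed(seed)
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    s <- paste(sample(names(p), length_bp, replace = TRUE, prob = p),
               collapse = "")
    out <- Biostrings::DNAStringSet(s)
    names(out) <- id
    out
}

#' Substitution-mutated copy of nucleotide sequences
#'
#' Substitutes each position independently with probability `sub_rate`,
#' always to a different base (no indels), so expected identity to the
#' original is 100 * (1 - sub_rate) percent.
#'
#' @param seqs [Biostrings::DNAStringSet].
#' @param sub_rate per-base substitution probability.
#' @param seed integer seed.
#' @return Mutated [Biostrings::DNAStringSet].
#' @export
mutateGenome <- function(seqs, sub_rate, seed = 1L) {
    set.seed(seed)
    out <- vapply(as.character(seqs), function(s) {
        ch <- strsplit(s, "")[[1]]
        hit <- which(stats::runif(length(ch)) < sub_rate)
        for (i in hit)
            ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
        paste(ch, collapse = "")
    }, character(1))
    res <- Biostrings::DNAStringSet(unname(out))
    names(res) <- names(seqs)
    res
}

#' Random synthetic proteome
#'
#' @param n_proteins number of proteins.
#' @param length_aa protein length (single value or range c(min, max)).
#' @param seed integer seed.
#' @return Named [Biostrings::AAStringSet].
#' @export
randomProteome <- function(n_proteins = 100L, length_aa = c(200L, 400L),
                           seed = 1L) {
    set.seed(seed)
    if (length(length_aa) == 1L) length_aa <- rep(length_aa, 2L)
    lens <- sample(seq(length_aa[1], length_aa[2]), n_proteins,
                   replace = TRUE)
    seqs <- vapply(lens, function(l)
        paste(sample(.AA_ALPHABET, l, replace = TRUE), collapse = ""),
        character(1))
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- sprintf("prot%03d", seq_len(n_proteins))
    out
}

#' Substitution-mutated copy of protein sequences
#'
#' @param proteome [Biostrings::AAStringSet].
#' @param sub_rate per-residue substitution probability (to a different
#'   residue; no indels).
#' @param seed integer seed.
#' @return Mutated [Biostrings::AAStringSet].
#' @export
mutateProteome <- function(proteome, sub_rate, seed = 1L) {
    set.seed(seed)
    out <- vapply(as.character(proteome), function(s) {
        ch <- strsplit(s, "")[[1]]
        hit <- which(stats::runif(length(ch)) < sub_rate)
        for (i in hit)
            ch[i] <- sample(setdiff(.AA_ALPHABET, ch[i]), 1)
        paste(ch, collapse = "")
    }, character(1))
    res <- Biostrings::AAStringSet(unname(out))
    names(res) <- names(proteome)
    res
}

#' Sample error-free reads from a genome
#'
#' Uniform start positions; each read is reverse-complemented with
#' probability 0.5 when `both_strands` is TRUE.
#'
#' @param contigs [Biostrings::DNAStringSet].
#' @param n number of reads.
#' @param read_length read length, bp.
#' @param seed integer seed.
#' @param both_strands sample from both strands (default TRUE).
#' @return Named [Biostrings::DNAStringSet] of reads.
#' @export
sampleReads <- function(contigs, n, read_length = 500L, seed = 1L,
                        both_strands = TRUE) {
    set.seed(seed)
    w <- Biostrings::width(contigs)
    if (all(w < read_length))
        stop("all contigs are shorter than read_length")
    pick <- sample(which(w >= read_length), n, replace = TRUE,
                   prob = w[w >= read_length])
    starts <- vapply(pick, function(i)
        sample.int(w[i] - read_length + 1L, 1L), integer(1))
    reads <- Biostrings::DNAStringSet(vapply(seq_len(n), function(k)
        as.character(Biostrings::subseq(contigs[[pick[k]]], starts[k],
                                        starts[k] + read_length - 1L)),
        character(1)))
    if (both_strands) {
        flip <- stats::runif(n) < 0.5
        if (any(flip))
            reads[flip] <- Biostrings::reverseComplement(reads[flip])
    }
    names(reads) <- sprintf("read%04d", seq_len(n))
    reads
}

#' Synthetic SDIMO/pMMO marker reference panel
#'
#' Generates one random reference protein per marker family with the
#' canonical family-to-group mapping: tmoA (toluene MO, Group I), dmpN
#' (phenol hydroxylase, Group II), mmoX (sMMO, Group III), bmoX (butane MO,
#' Group III, after Thauera butanivorans), prmA from Gordonia sp. TY-5
#' (Group V) and from Mycobacterium sp. TY-6 (Group VI), and pmoA
#' (membrane-bound pMMO-like).  Sequences are random and mutually unrelated,
#' which keeps groups separable under identity-based assignment; real
#' reference sequences can be substituted by accession.
#'
#' @param seed integer seed.
#' @param length_aa reference protein length (default 300).
#' @return A [MarkerPanel-class] (synthetic sequences).
#' @export
syntheticMarkerPanel <- function(seed = 1L, length_aa = 300L) {
    manifest <- data.frame(
        id = c("tmoA_I", "dmpN_II", "mmoX_III", "bmoX_III",
               "prmA_V", "prmA_VI", "pmoA_pMMO"),
        family = c("tmoA", "dmpN", "mmoX", "bmoX", "prmA", "prmA", "pmoA"),
        group = c("I", "II", "III", "III", "V", "VI", "pMMO"),
        organism = c("Pseudomonas stutzeri OX1 (synthetic)",
                     "Pseudomonas sp. CF600 (synthetic)",
                     "Methylocella silvestris BL2 (synthetic)",
                     "Thauera butanivorans (synthetic)",
                     "Gordonia sp. TY-5 (synthetic)",
                     "Mycobacterium sp. TY-6 (synthetic)",
                     "Mycolicibacterium chubuense NBB4 (synthetic)"),
        stringsAsFactors = FALSE)
    set.seed(seed)
    seqs <- Biostrings::AAStringSet(vapply(seq_len(nrow(manifest)),
        function(i) paste(sample(.AA_ALPHABET, length_aa, replace = TRUE),
                          collapse = ""), character(1)))
    names(seqs) <- manifest$id
    markerPanel(manifest, seqs)
}

#' Plant diverged marker genes into a proteome
#'
#' Adds a substitution-mutated copy of each selected panel reference to a
#' proteome, emulating a MAG that encodes those markers.
#'
#' @param proteome [Biostrings::AAStringSet] background proteome.
#' @param panel A [MarkerPanel-class].
#' @param ids panel reference ids to plant.
#' @param sub_rate divergence of the planted copies (default 0.2, i.e. ~80%
#'   identity).
#' @param seed integer seed.
#' @return [Biostrings::AAStringSet] with planted copies named
#'   `planted_<id>`.
#' @export
plantMarkers <- function(proteome, panel, ids, sub_rate = 0.2, seed = 1L) {
    stopifnot(all(ids %in% names(panel@sequences)))
    planted <- mutateProteome(panel@sequences[ids], sub_rate, seed)
    names(planted) <- paste0("planted_", ids)
    c(proteome, planted)
}
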