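## Internal wrappers around the NCBI BLAST+ command-line suite, used for the
## database-search steps (fragment ANI, RBH AAI, marker screening, fragment
## recruitment).  Low-complexity masking is disabled so identity estimates
## on arbitrary sequence content are unbiased.

.BLAST6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

.requireBlast <- function(programs = c("makeblastdb", "blastn", "blastp")) {
    missing <- programs[!nzchar(Sys.which(programs))]
    if (length(missing))
        stop("NCBI BLAST+ program(s) not found on PATH: ",
             paste(missing, collapse = ", "))
    invisible(TRUE)
}

.writeFastaTmp <- function(seqs, path) {
    if (is.character(seqs))
        seqs <- Biostrings::BStringSet(seqs)
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
        names(seqs) <- paste0("seq", seq_along(seqs))
    Biostrings::writeXStringSet(seqs, path, width = 60L)
    path
}

.makeBlastDb <- function(seqs, dbtype = c("nucl", "prot"),
                         dir = tempfile("blastdb")) {
    dbtype <- match.arg(dbtype)
    .requireBlast("makeblastdb")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "db.fasta")
    .writeFastaTmp(seqs, fa)
    out <- system2("makeblastdb",
                   c("-in", shQuote(fa), "-dbtype", dbtype,
                     "-out", shQuote(file.path(dir, "db"))),
                   stdout = TRUE, stderr = TRUE)
    if (!is.null(attr(out, "status")) && attr(out, "status") != 0)
        stop("makeblastdb failed: ", paste(out, collapse = "\n"))
    file.path(dir, "db")
}

## Runs blastn/blastp of `queries` against a prebuilt db; returns a
## data.frame in 12-column tabular (outfmt 6) layout, empty when no hits.
.blastTable <- function(queries, db,
                        program = c("blastn", "blastp"),
                        evalue = 10, extra = character()) {
    program <- match.arg(program)
    .requireBlast(program)
    qfa <- tempfile("query", fileext = ".fasta")
    on.exit(unlink(qfa), add = TRUE)
    .writeFastaTmp(queries, qfa)
    mask_off <- if (program == "blastn") c("-dust", "no") else c("-seg", "no")
    task <- if (program == "blastn") c("-task", "blastn") else character()
    outfile <- tempfile("hits", fileext = ".tsv")
    on.exit(unlink(outfile), add = TRUE)
    err <- system2(program,
                   c("-query", shQuote(qfa), "-db", shQuote(db),
                     "-outfmt", "6", "-evalue", format(evalue),
                     task, mask_off, extra, "-out", shQuote(outfile)),
                   stdout = TRUE, stderr = TRUE)
    if (!is.null(attr(err, "status")) && attr(err, "status") != 0)
        stop(program, " failed: ", paste(err, collapse = "\n"))
    if (!file.exists(outfile) || file.info(outfile)$size == 0)
        return(stats::setNames(
            data.frame(matrix(nrow = 0, ncol = 12)), .BLAST6_COLS))
    hits <- utils::read.table(outfile, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE,
                              col.names = .BLAST6_COLS)
    hits
}

## Best hit per query by bitscore, deterministic first-by-subject-id
## tie-break.
.bestHits <- function(hits) {
    if (nrow(hits) == 0L)
        return(hits)
    hits <- hits[order(hits$qseqid, -hits$bitscore, hits$sseqid), ]
    hits[!duplicated(hits$qseqid), , drop = FALSE]
}
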