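## Plain-text interchange: fraction-table TSV, pool TSV, hit tables, MAG
## metadata, marker panels, genome FASTA, and YAML run configuration.

#' Write a fraction table as TSV
#'
#' Columns: `vial_id`, `fraction`, `refractive_index`, `density_g_ml`,
#' `dna_ng`, then one count column per taxon.
#'
#' @param ft A [FractionTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFractionTable <- function(ft, path) {
    cd <- colData(ft)
    df <- data.frame(vial_id = metadata(ft)$vial_id,
                     fraction = cd$fraction,
                     refractive_index = cd$refractive_index,
                     density_g_ml = cd$density_g_ml,
                     dna_ng = cd$dna_ng,
                     t(assay(ft, "counts")), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a fraction table TSV
#'
#' @param path file written by [writeFractionTable()] (or real data in the
#'   same layout).
#' @return A [FractionTable-class].
#' @export
readFractionTable <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    meta_cols <- c("vial_id", "fraction", "refractive_index",
                   "density_g_ml", "dna_ng")
    taxa <- setdiff(names(df), meta_cols)
    FractionTable(counts = t(as.matrix(df[, taxa, drop = FALSE])),
                  fraction = df$fraction,
                  refractive_index = df$refractive_index,
                  density_g_ml = df$density_g_ml,
                  dna_ng = df$dna_ng,
                  vial_id = df$vial_id[1])
}

#' Write ground-truth labels of a simulated dataset
#'
#' Columns: `taxon`, `substrate`, `true_label`.
#'
#' @param dataset A [SIPDataset-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(dataset, path) {
    community <- metadata(dataset)$community
    design <- metadata(dataset)$design
    rows <- do.call(rbind, lapply(design@substrates$name, function(sub) {
        lab <- vapply(strsplit(community$consumes, ";", fixed = TRUE),
                      function(x) sub %in% x, logical(1)) &
            community$atom_excess > 0
        data.frame(taxon = community$id, substrate = sub, true_label = lab)
    }))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a heavy/light pool pair as TSV
#'
#' Columns: `vial_id`, `pool`, `taxon`, `count`.
#'
#' @param pool list from [poolFractions()].
#' @param vial_id vial identifier.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePoolPair <- function(pool, vial_id, path) {
    df <- rbind(
        data.frame(vial_id = vial_id, pool = "heavy",
                   taxon = names(pool$heavy_counts),
                   count = unname(pool$heavy_counts)),
        data.frame(vial_id = vial_id, pool = "light",
                   taxon = names(pool$light_counts),
                   count = unname(pool$light_counts)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read MAG quality metadata
#'
#' @param path TSV with columns `id`, `completeness`, `contamination` (and
#'   optionally more, which are kept).
#' @return data.frame.
#' @export
readMAGMetadata <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
}

#' Read a genome FASTA into a GenomeRecord
#'
#' @param path FASTA of contigs.
#' @param id record identifier (default: file name without extension).
#' @param proteome_path optional protein FASTA.
#' @param completeness,contamination optional quality metadata, percent.
#' @return A [GenomeRecord-class].
#' @export
readGenomeFasta <- function(path, id = sub("\\.[^.]*$", "", basename(path)),
                            proteome_path = NULL,
                            completeness = NA_real_,
                            contamination = NA_real_) {
    genomeRecord(id, contigs = Biostrings::readDNAStringSet(path),
                 proteome = if (is.null(proteome_path))
                     Biostrings::AAStringSet()
                 else Biostrings::readAAStringSet(proteome_path),
                 completeness = completeness, contamination = contamination)
}

#' Read a marker panel from a manifest TSV and protein FASTA
#'
#' @param manifest_path TSV with columns `id`, `family`, `group`,
#'   `organism`.
#' @param fasta_path protein FASTA named by manifest ids.
#' @return A [MarkerPanel-class].
#' @export
readMarkerPanel <- function(manifest_path, fasta_path) {
    markerPanel(utils::read.table(manifest_path, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE),
                Biostrings::readAAStringSet(fasta_path))
}

#' Write alignment/search hits in 12-column tabular layout
#'
#' @param hits data.frame in outfmt-6 layout (as returned internally by the
#'   search wrappers).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHitsTable <- function(hits, path) {
    utils::write.table(hits, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a YAML run configuration
#'
#' The YAML mirrors the [gradientParams()] and [sipDesign()] field names
#' under top-level keys `gradient` and `design`; missing fields take the
#' package defaults.
#'
#' @param path YAML file.
#' @return list with elements `params` ([GradientParams-class]) and `design`
#'   ([SIPDesign-class]).
#' @export
readSIPConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    gp <- do.call(gradientParams, cfg$gradient %||% list())
    dn <- cfg$design %||% list()
    if (!is.null(dn$substrates))
        dn$substrates <- do.call(rbind, lapply(dn$substrates, function(s)
            data.frame(name = s$name, n_carbons = as.integer(s$n_carbons))))
    list(params = gp, design = do.call(sipDesign, dn))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
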