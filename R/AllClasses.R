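#' @import methods
#' @importFrom S4Vectors SimpleList DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

## ---------------------------------------------------------------------------
## Gradient physics parameters
## ---------------------------------------------------------------------------

#' Parameters of the CsCl isopycnic gradient model
#'
#' Houses the physical constants used to place a taxon's DNA in the gradient
#' and to convert between refractive index and buoyant density.  The GC
#' dependence of buoyant density uses the Schildkraut-type affine relation
#' rho = gc_intercept + gc_slope * GC, and full \eqn{^{13}}C labelling shifts a
#' band up by `full_label_shift` g/ml.  Refractive index relates to density
#' through density = ri_slope * RI - ri_intercept.
#'
#' @slot n_fractions integer, number of equal-width fractions collected.
#' @slot density_min,density_max numeric, gradient span in g/ml.
#' @slot band_sigma numeric, Gaussian diffusion width of a DNA band (g/ml).
#' @slot gc_slope,gc_intercept numeric, GC-to-density affine coefficients.
#' @slot full_label_shift numeric, density shift (g/ml) at 100 atom% excess.
#' @slot ri_slope,ri_intercept numeric, refractive-index conversion
#'   coefficients.
#' @slot background numeric, fraction of each taxon's DNA smeared uniformly
#'   across all fractions (models the background of unlabelled DNA always
#'   present in heavy fractions of real SIP gradients; 0 gives a pure
#'   Gaussian band).
#'
#' @export
setClass("GradientParams", representation(
    n_fractions = "integer",
    density_min = "numeric",
    density_max = "numeric",
    band_sigma = "numeric",
    gc_slope = "numeric",
    gc_intercept = "numeric",
    full_label_shift = "numeric",
    ri_slope = "numeric",
    ri_intercept = "numeric",
    background = "numeric"
))

setValidity("GradientParams", function(object) {
    msg <- NULL
    if (object@n_fractions < 2L)
        msg <- c(msg, "n_fractions must be >= 2")
    if (!(object@density_min < object@density_max))
        msg <- c(msg, "density_min must be < density_max")
    if (object@band_sigma <= 0)
        msg <- c(msg, "band_sigma must be > 0")
    if (object@full_label_shift < 0)
        msg <- c(msg, "full_label_shift must be >= 0")
    if (object@ri_slope <= 0)
        msg <- c(msg, "ri_slope must be > 0")
    if (object@background < 0 || object@background >= 1)
        msg <- c(msg, "background must lie in [0, 1)")
    if (is.null(msg)) TRUE else msg
})

#' Construct gradient parameters
#'
#' Defaults span 1.696-1.756 g/ml in 12 equal fractions so that the
#' heavy-DNA window (1.7296-1.7491 g/ml) covers four fraction midpoints and
#' the light window (1.7123-1.7216 g/ml) two, reproducing the 3-4 heavy and
#' 2-3 light fractions typically pooled from a 12-fraction SIP gradient.
#'
#' @param n_fractions number of fractions (default 12).
#' @param density_min,density_max gradient density span, g/ml.
#' @param band_sigma band diffusion width, g/ml.
#' @param gc_slope,gc_intercept GC-to-density coefficients (g/ml per GC
#'   fraction; g/ml).
#' @param full_label_shift density shift at 100 atom% excess, g/ml.
#' @param ri_slope,ri_intercept refractive-index conversion coefficients.
#' @param background fraction of each taxon's DNA smeared uniformly across
#'   fractions (default 0.02), emulating the unlabelled-DNA background seen
#'   in heavy fractions of real gradients.
#' @return A [GradientParams-class] object.
#' @examples
#' gradientParams()
#' @export
gradientParams <- function(n_fractions = 12L,
                           density_min = 1.696, density_max = 1.756,
                           band_sigma = 0.004,
                           gc_slope = 0.098, gc_intercept = 1.660,
                           full_label_shift = 0.036,
                           ri_slope = 10.9276, ri_intercept = 13.593,
                           background = 0.02) {
    new("GradientParams",
        n_fractions = as.integer(n_fractions),
        density_min = density_min, density_max = density_max,
        band_sigma = band_sigma,
        gc_slope = gc_slope, gc_intercept = gc_intercept,
        full_label_shift = full_label_shift,
        ri_slope = ri_slope, ri_intercept = ri_intercept,
        background = background)
}

setMethod("show", "GradientParams", function(object) {
    cat("GradientParams:", object@n_fractions, "fractions over [",
        object@density_min, ",", object@density_max, "] g/ml; band sigma",
        object@band_sigma, "\n  GC model:", object@gc_intercept, "+",
        object@gc_slope, "* GC; full-label shift", object@full_label_shift,
        "g/ml\n")
})

## ---------------------------------------------------------------------------
## Experimental design
## ---------------------------------------------------------------------------

#' SIP incubation design
#'
#' @slot substrates data.frame with columns `name` and `n_carbons`.
#' @slot isotopes character, isotope treatments (default "12C" and "13C").
#' @slot replicates integer, vials per substrate x isotope.
#' @slot depth integer, sequencing reads per fraction.
#' @slot seed integer, base seed from which per-vial streams are derived.
#' @export
setClass("SIPDesign", representation(
    substrates = "data.frame",
    isotopes = "character",
    replicates = "integer",
    depth = "integer",
    seed = "integer"
))

setValidity("SIPDesign", function(object) {
    msg <- NULL
    if (!all(c("name", "n_carbons") %in% names(object@substrates)))
        msg <- c(msg, "substrates needs columns 'name' and 'n_carbons'")
    if (object@replicates < 1L)
        msg <- c(msg, "replicates must be >= 1")
    if (object@depth < 0L)
        msg <- c(msg, "depth must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SIP incubation design
#'
#' Defaults mirror a duplicate-vial design with ethane and propane, each as
#' \eqn{^{12}}C and \eqn{^{13}}C treatments.
#'
#' @param substrates data.frame with columns `name`, `n_carbons`.
#' @param isotopes character vector of isotope treatments.
#' @param replicates vials per substrate x isotope combination.
#' @param depth sequencing reads per gradient fraction.
#' @param seed integer base seed.
#' @return A [SIPDesign-class] object.
#' @examples
#' sipDesign(replicates = 2, depth = 5e4)
#' @export
sipDesign <- function(substrates = data.frame(
                          name = c("ethane", "propane"),
                          n_carbons = c(2L, 3L)),
                      isotopes = c("12C", "13C"),
                      replicates = 2L, depth = 50000L, seed = 1L) {
    new("SIPDesign", substrates = substrates, isotopes = isotopes,
        replicates = as.integer(replicates), depth = as.integer(depth),
        seed = as.integer(seed))
}

setMethod("show", "SIPDesign", function(object) {
    cat("SIPDesign:", nrow(object@substrates), "substrates (",
        paste(object@substrates$name, collapse = ", "), ") x",
        length(object@isotopes), "isotopes x", object@replicates,
        "replicates; depth", object@depth, "reads/fraction\n")
})

## ---------------------------------------------------------------------------
## Pooling windows
## ---------------------------------------------------------------------------

#' Heavy/light buoyant-density pooling windows
#'
#' Closed density intervals (g/ml) into which gradient fractions are pooled.
#' Defaults are the heavy (1.7296-1.7491 g/ml) and light (1.7123-1.7216
#' g/ml) DNA windows used for gaseous-alkane SIP gradients.
#'
#' @slot heavy,light numeric length-2 closed intervals, g/ml.
#' @export
setClass("PoolWindows", representation(heavy = "numeric", light = "numeric"))

setValidity("PoolWindows", function(object) {
    msg <- NULL
    if (length(object@heavy) != 2L || length(object@light) != 2L)
        msg <- c(msg, "heavy and light must be length-2 intervals")
    else {
        if (object@heavy[1] > object@heavy[2] ||
            object@light[1] > object@light[2])
            msg <- c(msg, "interval bounds must be ordered low <= high")
        if (!(object@heavy[1] > object@light[2]))
            msg <- c(msg, "windows must be disjoint with heavy denser")
    }
    if (is.null(msg)) TRUE else msg
})

#' @param heavy,light closed density intervals c(low, high), g/ml.
#' @return A [PoolWindows-class] object.
#' @rdname PoolWindows-class
#' @examples
#' poolWindows()
#' @export
poolWindows <- function(heavy = c(1.7296, 1.7491),
                        light = c(1.7123, 1.7216)) {
    new("PoolWindows", heavy = sort(heavy), light = sort(light))
}

setMethod("show", "PoolWindows", function(object) {
    cat("PoolWindows: heavy [", object@heavy[1], ",", object@heavy[2],
        "] g/ml; light [", object@light[1], ",", object@light[2], "] g/ml\n")
})

## ---------------------------------------------------------------------------
## Fraction table (one vial) and dataset (one experiment)
## ---------------------------------------------------------------------------

#' Per-vial gradient fraction table
#'
#' A [SummarizedExperiment::SummarizedExperiment] with taxa as rows and
#' gradient fractions as columns (fraction 1 = densest).  The `counts` assay
#' holds per-taxon sequencing counts; `colData` carries `fraction`,
#' `refractive_index`, `density_g_ml` and `dna_ng`; `metadata` carries
#' `vial_id`, `substrate`, `isotope`, `replicate` and (for simulated vials)
#' the ground-truth `labelled_taxa`.
#'
#' @export
setClass("FractionTable", contains = "SummarizedExperiment")

setValidity("FractionTable", function(object) {
    msg <- NULL
    need <- c("fraction", "refractive_index", "density_g_ml", "dna_ng")
    if (!all(need %in% names(colData(object))))
        msg <- c(msg, paste("colData needs columns:",
                            paste(need, collapse = ", ")))
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else if (any(assay(object, "counts") < 0))
        msg <- c(msg, "counts must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' Build a FractionTable
#'
#' @param counts taxa x fraction matrix of non-negative counts.
#' @param fraction integer fraction indices (1 = densest).
#' @param refractive_index,density_g_ml,dna_ng per-fraction measurements.
#' @param vial_id,substrate,isotope,replicate vial annotation.
#' @param labelled_taxa character, ground-truth labelled taxa (simulation).
#' @return A [FractionTable-class].
#' @export
FractionTable <- function(counts, fraction, refractive_index, density_g_ml,
                          dna_ng, vial_id = "vial", substrate = NA_character_,
                          isotope = NA_character_, replicate = NA_integer_,
                          labelled_taxa = character()) {
    se <- SummarizedExperiment(
        assays = list(counts = as.matrix(counts)),
        colData = DataFrame(fraction = as.integer(fraction),
                            refractive_index = refractive_index,
                            density_g_ml = density_g_ml,
                            dna_ng = dna_ng))
    metadata(se) <- list(vial_id = vial_id, substrate = substrate,
                         isotope = isotope, replicate = replicate,
                         labelled_taxa = labelled_taxa)
    new("FractionTable", se)
}

setMethod("show", "FractionTable", function(object) {
    md <- metadata(object)
    cat("FractionTable for vial", md$vial_id, "(", md$substrate, md$isotope,
        "rep", md$replicate, "):", nrow(object), "taxa x", ncol(object),
        "fractions;", round(sum(colData(object)$dna_ng), 2), "ng DNA\n")
})

#' Simulated SIP dataset: one FractionTable per vial
#'
#' A [S4Vectors::SimpleList] of [FractionTable-class] objects, one per
#' substrate x isotope x replicate vial, with the community, design and
#' gradient parameters in `metadata`.
#'
#' @export
setClass("SIPDataset", contains = "SimpleList",
         prototype = prototype(elementType = "FractionTable"))

setMethod("show", "SIPDataset", function(object) {
    cat("SIPDataset with", length(object), "vials:\n ",
        paste(names(object), collapse = "\n  "), "\n")
})

## ---------------------------------------------------------------------------
## Headspace gas series
## ---------------------------------------------------------------------------

#' Headspace gas concentration time series for one vial
#'
#' @slot vial_id character.
#' @slot substrate character, gas name.
#' @slot n_carbons integer, carbon atoms per molecule.
#' @slot times numeric, days (strictly increasing).
#' @slot pct_v_v numeric, headspace concentration (% v/v) at each time.
#' @slot headspace_ml,sample_g numeric, headspace volume and sample mass.
#' @slot temperature_K,pressure_kPa numeric, ideal-gas conversion conditions.
#' @export
setClass("HeadspaceSeries", representation(
    vial_id = "character", substrate = "character", n_carbons = "integer",
    times = "numeric", pct_v_v = "numeric",
    headspace_ml = "numeric", sample_g = "numeric",
    temperature_K = "numeric", pressure_kPa = "numeric"
))

setValidity("HeadspaceSeries", function(object) {
    msg <- NULL
    if (length(object@times) != length(object@pct_v_v))
        msg <- c(msg, "times and pct_v_v must have equal length")
    if (length(object@times) > 1L && any(diff(object@times) <= 0))
        msg <- c(msg, "times must be strictly increasing")
    if (any(object@pct_v_v < 0))
        msg <- c(msg, "pct_v_v must be >= 0")
    if (object@sample_g <= 0)
        msg <- c(msg, "sample_g must be > 0")
    if (object@n_carbons < 1L)
        msg <- c(msg, "n_carbons must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' Construct a headspace series
#'
#' @param vial_id vial identifier.
#' @param substrate gas name.
#' @param n_carbons carbon atoms per molecule (ethane 2, propane 3).
#' @param times sampling times, days.
#' @param pct_v_v measured headspace concentration, % v/v.
#' @param headspace_ml headspace volume, ml.
#' @param sample_g fresh sample mass, g.
#' @param temperature_K,pressure_kPa conditions for the ideal-gas conversion.
#' @return A [HeadspaceSeries-class].
#' @export
headspaceSeries <- function(vial_id, substrate, n_carbons, times, pct_v_v,
                            headspace_ml = 100, sample_g = 2,
                            temperature_K = 298.15, pressure_kPa = 101.325) {
    new("HeadspaceSeries", vial_id = vial_id, substrate = substrate,
        n_carbons = as.integer(n_carbons), times = times, pct_v_v = pct_v_v,
        headspace_ml = headspace_ml, sample_g = sample_g,
        temperature_K = temperature_K, pressure_kPa = pressure_kPa)
}

setMethod("show", "HeadspaceSeries", function(object) {
    cat("HeadspaceSeries", object@vial_id, "(", object@substrate, "):",
        length(object@times), "time points over", max(object@times), "days;",
        "start", object@pct_v_v[1], "% v/v\n")
})

## ---------------------------------------------------------------------------
## Alignment scoring
## ---------------------------------------------------------------------------

#' Pairwise alignment scoring scheme
#'
#' @slot kind "nucleotide" or "protein".
#' @slot match,mismatch integer scores (nucleotide kind).
#' @slot matrix substitution matrix name (protein kind).
#' @slot gap_open,gap_extend non-negative gap penalties; a gap of length k
#'   costs gap_open + k * gap_extend.
#' @slot lambda,K Karlin-Altschul parameters for e-value estimation.
#' @export
setClass("ScoringScheme", representation(
    kind = "character", match = "numeric", mismatch = "numeric",
    matrix = "character", gap_open = "numeric", gap_extend = "numeric",
    lambda = "numeric", K = "numeric"
))

setValidity("ScoringScheme", function(object) {
    msg <- NULL
    if (!object@kind %in% c("nucleotide", "protein"))
        msg <- c(msg, "kind must be 'nucleotide' or 'protein'")
    if (object@gap_extend < 0 || object@gap_open < object@gap_extend)
        msg <- c(msg, "need gap_open >= gap_extend >= 0")
    if (object@lambda <= 0 || object@K <= 0)
        msg <- c(msg, "lambda and K must be > 0")
    if (is.null(msg)) TRUE else msg
})

#' Construct a scoring scheme
#'
#' Karlin-Altschul defaults are standard published values: lambda = 1.33,
#' K = 0.621 for nucleotide search and lambda = 0.267, K = 0.041 for gapped
#' BLOSUM62 protein search; e-values are therefore comparable to, but not
#' bit-identical with, BLAST's.
#'
#' @param kind "nucleotide" or "protein".
#' @param match,mismatch nucleotide scores (defaults +1/-2).
#' @param matrix protein substitution matrix name (default "BLOSUM62").
#' @param gap_open,gap_extend affine gap penalties (defaults 5, 2).
#' @param lambda,K Karlin-Altschul parameters (kind-specific defaults).
#' @return A [ScoringScheme-class].
#' @examples
#' scoringScheme("nucleotide")
#' scoringScheme("protein", gap_open = 11, gap_extend = 1)
#' @export
scoringScheme <- function(kind = c("nucleotide", "protein"),
                          match = 1, mismatch = -2, matrix = "BLOSUM62",
                          gap_open = 5, gap_extend = 2,
                          lambda = NULL, K = NULL) {
    kind <- match.arg(kind)
    if (is.null(lambda)) lambda <- if (kind == "nucleotide") 1.33 else 0.267
    if (is.null(K)) K <- if (kind == "nucleotide") 0.621 else 0.041
    new("ScoringScheme", kind = kind, match = match, mismatch = mismatch,
        matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
        lambda = lambda, K = K)
}

setMethod("show", "ScoringScheme", function(object) {
    sc <- if (object@kind == "nucleotide")
        paste0("match ", object@match, "/mismatch ", object@mismatch)
    else object@matrix
    cat("ScoringScheme (", object@kind, "): ", sc, "; gap ",
        object@gap_open, "/", object@gap_extend, "; lambda=", object@lambda,
        ", K=", object@K, "\n", sep = "")
})

#' Pairwise alignment result
#'
#' @slot query_id,subject_id sequence identifiers.
#' @slot type "global" or "local".
#' @slot score numeric alignment score.
#' @slot matches,mismatches,gap_columns integer column tallies; they sum to
#'   the alignment length.
#' @slot identity_pct percent identity (all-columns mode).
#' @slot evalue Karlin-Altschul e-value (local alignments; NA for global).
#' @slot query_start,query_end,subject_start,subject_end 0-based half-open
#'   aligned spans on the query/subject.
#' @slot aligned_query,aligned_subject gapped alignment strings.
#' @export
setClass("PairwiseHit", representation(
    query_id = "character", subject_id = "character", type = "character",
    score = "numeric", matches = "integer", mismatches = "integer",
    gap_columns = "integer", identity_pct = "numeric", evalue = "numeric",
    query_start = "integer", query_end = "integer",
    subject_start = "integer", subject_end = "integer",
    aligned_query = "character", aligned_subject = "character"
))

setValidity("PairwiseHit", function(object) {
    len <- object@matches + object@mismatches + object@gap_columns
    if (len != nchar(object@aligned_query))
        return("matches + mismatches + gap_columns must equal alignment length")
    if (!is.na(object@identity_pct) &&
        (object@identity_pct < 0 || object@identity_pct > 100))
        return("identity_pct must lie in [0, 100]")
    TRUE
})

setMethod("show", "PairwiseHit", function(object) {
    cat("PairwiseHit (", object@type, ") ", object@query_id, " vs ",
        object@subject_id, ": score ", object@score, ", identity ",
        round(object@identity_pct, 2), "% (", object@matches, "m/",
        object@mismatches, "mm/", object@gap_columns, "gap)",
        if (!is.na(object@evalue)) paste0(", E=",
            signif(object@evalue, 3)), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## Genomes and marker panels
## ---------------------------------------------------------------------------

#' Genome or MAG record
#'
#' @slot id character identifier.
#' @slot contigs [Biostrings::DNAStringSet] of contig sequences.
#' @slot proteome [Biostrings::AAStringSet] of predicted proteins (may be
#'   empty).
#' @slot completeness,contamination numeric quality estimates in percent
#'   (consumed as given; NA when unknown).
#' @export
setClass("GenomeRecord", representation(
    id = "character", contigs = "DNAStringSet", proteome = "AAStringSet",
    completeness = "numeric", contamination = "numeric"
))

setValidity("GenomeRecord", function(object) {
    msg <- NULL
    if (!is.na(object@completeness) &&
        (object@completeness < 0 || object@completeness > 100))
        msg <- c(msg, "completeness must lie in [0, 100]")
    if (!is.na(object@contamination) && object@contamination < 0)
        msg <- c(msg, "contamination must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Construct a genome record
#'
#' @param id genome/MAG identifier.
#' @param contigs DNAStringSet (or character) of contigs.
#' @param proteome AAStringSet (or character) of proteins; optional.
#' @param completeness,contamination percent quality estimates; optional.
#' @return A [GenomeRecord-class].
#' @export
genomeRecord <- function(id, contigs = Biostrings::DNAStringSet(),
                         proteome = Biostrings::AAStringSet(),
                         completeness = NA_real_, contamination = NA_real_) {
    new("GenomeRecord", id = id,
        contigs = Biostrings::DNAStringSet(contigs),
        proteome = Biostrings::AAStringSet(proteome),
        completeness = as.numeric(completeness),
        contamination = as.numeric(contamination))
}

setMethod("show", "GenomeRecord", function(object) {
    cat("GenomeRecord", object@id, ":", length(object@contigs), "contigs (",
        sum(Biostrings::width(object@contigs)), "bp ),",
        length(object@proteome), "proteins; completeness",
        object@completeness, "%, contamination", object@contamination, "%\n")
})

#' SDIMO / pMMO marker reference panel
#'
#' A panel of large (alpha) subunit reference proteins used for marker
#' screening and nearest-reference group assignment.
#'
#' @slot manifest data.frame with columns `id`, `family`, `group`,
#'   `organism`.
#' @slot sequences [Biostrings::AAStringSet], names matching `manifest$id`.
#' @export
setClass("MarkerPanel", representation(
    manifest = "data.frame", sequences = "AAStringSet"
))

## SDIMO groups: I aromatic/alkene, II phenol, III sMMO/butane, IV
## ethene/propene, V and VI propane; pMMO = membrane-bound Cu monooxygenase.
.VALID_GROUPS <- c("I", "II", "III", "IV", "V", "VI", "pMMO")
.VALID_FAMILIES <- c("mmoX", "bmoX", "prmA", "dmpN", "tmoA", "pmoA")

setValidity("MarkerPanel", function(object) {
    msg <- NULL
    need <- c("id", "family", "group", "organism")
    if (!all(need %in% names(object@manifest)))
        msg <- c(msg, paste("manifest needs columns:",
                            paste(need, collapse = ", ")))
    else {
        if (!all(object@manifest$group %in% .VALID_GROUPS))
            msg <- c(msg, "groups must be I-VI or pMMO")
        if (!all(object@manifest$family %in% .VALID_FAMILIES))
            msg <- c(msg, paste("families must be among:",
                                paste(.VALID_FAMILIES, collapse = ", ")))
        if (!setequal(object@manifest$id, names(object@sequences)))
            msg <- c(msg, "sequence names must match manifest ids")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a marker panel
#'
#' @param manifest data.frame with columns `id`, `family`, `group`,
#'   `organism`.
#' @param sequences AAStringSet named by `manifest$id`.
#' @return A [MarkerPanel-class].
#' @export
markerPanel <- function(manifest, sequences) {
    new("MarkerPanel", manifest = manifest,
        sequences = Biostrings::AAStringSet(sequences))
}

setMethod("show", "MarkerPanel", function(object) {
    cat("MarkerPanel:", nrow(object@manifest), "references, families {",
        paste(sort(unique(object@manifest$family)), collapse = ", "),
        "}, groups {",
        paste(sort(unique(object@manifest$group)), collapse = ", "), "}\n")
})
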