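## Three-criterion classifier of 13C-labelled taxa.

#' Relative abundance within a pool
#'
#' @param counts named non-negative per-taxon counts.
#' @return Named percentages summing to 100.
#' @examples
#' relativeAbundance(c(A = 27, B = 73))
#' @export
relativeAbundance <- function(counts) {
    if (any(counts < 0))
        stop("counts must be non-negative")
    total <- sum(counts)
    if (total <= 0)
        stop("undefined pool: total count is zero")
    100 * counts / total
}

#' Classify taxa as 13C-labelled
#'
#' Applies the three labelling criteria to the four pool abundances of each
#' taxon (all percentages within their pool):
#' \enumerate{
#'   \item relative abundance in the heavy pool of the \eqn{^{13}}C
#'     incubation exceeds `min_heavy_pct` (strict);
#'   \item heavy abundance of the \eqn{^{13}}C incubation exceeds its light
#'     abundance (strict);
#'   \item the heavy-light abundance difference of the \eqn{^{13}}C
#'     incubation exceeds that of the \eqn{^{12}}C incubation (strict).
#' }
#' A taxon is labelled iff all three hold.  Taxa with any missing abundance
#' are marked uncallable and never labelled.
#'
#' @param quads data.frame with columns `taxon`, `heavy_13C`, `light_13C`,
#'   `heavy_12C`, `light_12C` (percent, each pool summing to 100).
#' @param min_heavy_pct criterion-1 threshold in percent (default 1.0).
#' @return The input with added logical columns `c1`, `c2`, `c3`,
#'   `callable` and `labelled`.
#' @examples
#' q <- data.frame(taxon = "t", heavy_13C = 2, light_13C = 0.5,
#'                 heavy_12C = 0.8, light_12C = 0.9)
#' classifyLabelled(q)$labelled
#' @export
classifyLabelled <- function(quads, min_heavy_pct = 1.0) {
    need <- c("taxon", "heavy_13C", "light_13C", "heavy_12C", "light_12C")
    if (!all(need %in% names(quads)))
        stop("quads must have columns: ", paste(need, collapse = ", "))
    callable <- stats::complete.cases(
        quads[, c("heavy_13C", "light_13C", "heavy_12C", "light_12C")])
    c1 <- quads$heavy_13C > min_heavy_pct
    c2 <- quads$heavy_13C > quads$light_13C
    c3 <- (quads$heavy_13C - quads$light_13C) >
        (quads$heavy_12C - quads$light_12C)
    out <- quads
    out$c1 <- c1 & callable
    out$c2 <- c2 & callable
    out$c3 <- c3 & callable
    out$callable <- callable
    out$labelled <- out$c1 & out$c2 & out$c3
    out
}

#' Build abundance quads from a simulated SIP dataset and classify
#'
#' Pools every vial of the given substrate into heavy/light windows,
#' converts pools to relative abundances, averages across replicate vials
#' within each isotope treatment (the default replicate handling; set
#' `replicate_rule = "all"` to require every replicate pair to pass), and
#' applies [classifyLabelled()].
#'
#' @param dataset A [SIPDataset-class] from [simulateExperiment()].
#' @param substrate substrate name to classify.
#' @param windows A [PoolWindows-class].
#' @param min_heavy_pct criterion-1 threshold, percent.
#' @param replicate_rule "average" (default) averages pool abundances across
#'   replicates before the criteria; "all" applies the criteria per
#'   replicate pairing and labels a taxon only if every pairing passes.
#' @return The [classifyLabelled()] data.frame; attribute `truth` carries
#'   the ground-truth labelled taxa of the \eqn{^{13}}C vials.
#' @examples
#' cm <- simulateCommunity(seed = 1)
#' ds <- simulateExperiment(cm, sipDesign(depth = 1e4, seed = 1))
#' calls <- callLabelledTaxa(ds, "ethane")
#' calls$taxon[calls$labelled]
#' @export
callLabelledTaxa <- function(dataset, substrate, windows = poolWindows(),
                             min_heavy_pct = 1.0,
                             replicate_rule = c("average", "all")) {
    replicate_rule <- match.arg(replicate_rule)
    keep <- vapply(dataset, function(ft)
        identical(metadata(ft)$substrate, substrate), logical(1))
    if (!any(keep))
        stop("no vials for substrate '", substrate, "' in the dataset")
    vials <- dataset[keep]
    iso <- vapply(vials, function(ft) metadata(ft)$isotope, character(1))
    poolPct <- function(ft) {
        pp <- poolFractions(ft, windows)
        if (!pp$usable)
            stop("unusable vial ", metadata(ft)$vial_id, ": ", pp$status)
        list(heavy = relativeAbundance(pp$heavy_counts),
             light = relativeAbundance(pp$light_counts))
    }
    p13 <- lapply(vials[iso == "13C"], poolPct)
    p12 <- lapply(vials[iso == "12C"], poolPct)
    if (!length(p13) || !length(p12))
        stop("need both 12C and 13C vials for substrate '", substrate, "'")
    taxa <- names(p13[[1]]$heavy)
    avg <- function(lst, pool)
        Reduce(`+`, lapply(lst, `[[`, pool)) / length(lst)
    quadsOf <- function(a13, a12)
        data.frame(taxon = taxa,
                   heavy_13C = unname(a13$heavy), light_13C = unname(a13$light),
                   heavy_12C = unname(a12$heavy), light_12C = unname(a12$light))
    if (replicate_rule == "average") {
        calls <- classifyLabelled(quadsOf(
            list(heavy = avg(p13, "heavy"), light = avg(p13, "light")),
            list(heavy = avg(p12, "heavy"), light = avg(p12, "light"))),
            min_heavy_pct)
    } else {
        per <- mapply(function(a13, a12)
            classifyLabelled(quadsOf(a13, a12), min_heavy_pct)$labelled,
            p13, p12[seq_along(p13)], SIMPLIFY = TRUE)
        calls <- classifyLabelled(quadsOf(
            list(heavy = avg(p13, "heavy"), light = avg(p13, "light")),
            list(heavy = avg(p12, "heavy"), light = avg(p12, "light"))),
            min_heavy_pct)
        calls$labelled <- rowSums(as.matrix(per)) == ncol(as.matrix(per))
    }
    truth <- unique(unlist(lapply(vials[iso == "13C"],
                                  function(ft) metadata(ft)$labelled_taxa)))
    attr(calls, "truth") <- truth
    calls
}

#' Confusion-matrix recovery of labelling calls against ground truth
#'
#' @param calls data.frame from [classifyLabelled()] (columns `taxon`,
#'   `labelled`).
#' @param truth character vector of truly labelled taxa.
#' @return list with `sensitivity`, `specificity`, `fdr` (NaN where
#'   undefined) and the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @examples
#' calls <- data.frame(taxon = c("a", "b"), labelled = c(TRUE, FALSE))
#' evaluateRecovery(calls, truth = "a")
#' @export
evaluateRecovery <- function(calls, truth) {
    taxa <- calls$taxon
    if (length(truth) && !any(truth %in% taxa))
        stop("truth taxa are disjoint from the call set")
    pos <- calls$labelled
    is_true <- taxa %in% truth
    tp <- sum(pos & is_true); fp <- sum(pos & !is_true)
    fn <- sum(!pos & is_true); tn <- sum(!pos & !is_true)
    list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NaN,
         fdr = if (tp + fp > 0) fp / (tp + fp) else NaN,
         tp = tp, fp = fp, tn = tn, fn = fn)
}
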