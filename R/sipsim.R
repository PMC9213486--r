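## Forward simulator of a CsCl gradient DNA-SIP experiment.
##
## The community is a plain data.frame ("community profile") with one row per
## taxon and columns:
##   id            character taxon identifier
##   gc            genomic GC content, fraction in [0, 1]
##   rel_abundance community relative abundance, fractions summing to 1
##   atom_excess   13C atom fraction excess when the taxon assimilates the
##                 labelled substrate (0 for non-consumers)
##   consumes      semicolon-separated substrate names the taxon assimilates
##                 ("" for none)

.checkCommunity <- function(community) {
    need <- c("id", "gc", "rel_abundance", "atom_excess", "consumes")
    if (!is.data.frame(community) || !all(need %in% names(community)))
        stop("community must be a data.frame with columns: ",
             paste(need, collapse = ", "))
    if (nrow(community) == 0L)
        stop("community must contain at least one taxon")
    if (any(community$gc < 0 | community$gc > 1))
        stop("gc must lie in [0, 1]")
    if (any(community$atom_excess < 0 | community$atom_excess > 1))
        stop("atom_excess must lie in [0, 1]")
    if (abs(sum(community$rel_abundance) - 1) > 1e-9)
        stop("rel_abundance must sum to 1 (got ",
             sum(community$rel_abundance), ")")
    invisible(community)
}

#' Equilibrium buoyant density of a taxon's DNA
#'
#' Affine CsCl model: density = gc_intercept + gc_slope * GC +
#' atom_excess * full_label_shift.  With defaults, an unlabelled genome of
#' 50% GC bands at 1.709 g/ml and shifts to 1.745 g/ml at 100 atom% excess.
#'
#' @param gc GC content, fraction in \[0, 1\] (vectorised).
#' @param atom_excess 13C atom fraction excess in \[0, 1\] (vectorised).
#' @param params A [GradientParams-class].
#' @return Buoyant density in g/ml.
#' @examples
#' taxonDensity(0.5, 0)      # 1.709
#' taxonDensity(0.5, 1)      # 1.745
#' @export
taxonDensity <- function(gc, atom_excess = 0, params = gradientParams()) {
    if (any(gc < 0 | gc > 1))
        stop("gc must lie in [0, 1]")
    if (any(atom_excess < 0 | atom_excess > 1))
        stop("atom_excess must lie in [0, 1]")
    params@gc_intercept + params@gc_slope * gc +
        atom_excess * params@full_label_shift
}

#' Simulate a synthetic SIP community with ground truth
#'
#' Draws a community profile emulating a natural-gas-seep microbial
#' community: `n_consumers` gaseous-alkane degraders at 5-15% relative
#' abundance each and full isotope labelling capacity, plus background taxa
#' with Dirichlet-distributed abundances.  GC contents are uniform over
#' `gc_range`.
#'
#' @param n_taxa total taxa (default 30).
#' @param n_consumers taxa that assimilate the labelled substrates
#'   (default 3).
#' @param substrates substrate names the consumers use (default both ethane
#'   and propane).
#' @param atom_excess 13C atom fraction excess of consumers (default 1).
#' @param gc_range GC content range (default 0.42-0.57).
#' @param consumer_abundance range of per-consumer relative abundance
#'   (default 0.05-0.15).
#' @param seed integer seed.
#' @return A community profile data.frame (see [simulateFractions()]).
#' @examples
#' head(simulateCommunity(seed = 1))
#' @export
simulateCommunity <- function(n_taxa = 30L, n_consumers = 3L,
                              substrates = c("ethane", "propane"),
                              atom_excess = 1.0,
                              gc_range = c(0.42, 0.57),
                              consumer_abundance = c(0.05, 0.15),
                              seed = 1L) {
    stopifnot(n_taxa >= 1L, n_consumers >= 0L, n_consumers <= n_taxa)
    set.seed(seed)
    id <- sprintf("taxon%02d", seq_len(n_taxa))
    gc <- stats::runif(n_taxa, gc_range[1], gc_range[2])
    consumer <- seq_len(n_consumers)
    ab <- numeric(n_taxa)
    ab[consumer] <- stats::runif(n_consumers, consumer_abundance[1],
                                 consumer_abundance[2])
    rest <- setdiff(seq_len(n_taxa), consumer)
    w <- stats::rgamma(length(rest), shape = 1)   # Dirichlet(1) weights
    ab[rest] <- (1 - sum(ab[consumer])) * w / sum(w)
    community <- data.frame(
        id = id, gc = gc, rel_abundance = ab,
        atom_excess = ifelse(seq_len(n_taxa) %in% consumer, atom_excess, 0),
        consumes = ifelse(seq_len(n_taxa) %in% consumer,
                          paste(substrates, collapse = ";"), ""),
        stringsAsFactors = FALSE)
    .checkCommunity(community)
}

## Deterministic per-vial RNG stream derived from (seed, substrate, isotope,
## replicate); kept below 2^31 - 1.
.vialSeed <- function(seed, substrate_idx, isotope_idx, replicate) {
    (as.numeric(seed) * 10007 + substrate_idx * 1009 +
        isotope_idx * 101 + replicate) %% 2147483647
}

#' Simulate gradient fractionation of one vial
#'
#' Each taxon's DNA mass (total_dna_ng * rel_abundance) is spread over the
#' fraction intervals in proportion to the integral of a Gaussian band
#' centred at [taxonDensity()] with standard deviation `band_sigma`; band
#' mass falling outside the gradient span is truncated and renormalised so
#' mass is conserved.  Per-fraction read counts are a multinomial draw of
#' size round(depth * fraction mass share) with per-taxon probabilities
#' proportional to mass in the fraction.  Fractions are numbered 1 =
#' densest, matching heavy-first fraction collection, and the refractive
#' index is back-computed from the fraction midpoint density.
#'
#' @param community community profile data.frame (see package docs); the
#'   `atom_excess` column is used as-is (set it to 0 to emulate a
#'   \eqn{^{12}}C control vial).
#' @param params A [GradientParams-class].
#' @param depth total sequencing reads for the vial, split across fractions.
#' @param total_dna_ng total DNA mass loaded on the gradient, ng.
#' @param seed integer seed for the vial's RNG stream.
#' @param vial_id,substrate,isotope,replicate vial annotation stored in the
#'   result metadata.
#' @return A [FractionTable-class].
#' @examples
#' cm <- simulateCommunity(seed = 1)
#' ft <- simulateFractions(cm, depth = 1e4, seed = 1)
#' ft
#' @export
simulateFractions <- function(community, params = gradientParams(),
                              depth = 50000L, total_dna_ng = 500,
                              seed = 1L, vial_id = "vial",
                              substrate = NA_character_,
                              isotope = NA_character_,
                              replicate = NA_integer_) {
    .checkCommunity(community)
    if (depth < 0)
        stop("depth must be >= 0")
    if (params@band_sigma <= 0)
        stop("band_sigma must be > 0")
    n <- params@n_fractions
    bounds <- seq(params@density_min, params@density_max, length.out = n + 1)
    lower <- bounds[-(n + 1)]
    upper <- bounds[-1]
    mid <- (lower + upper) / 2

    centre <- taxonDensity(community$gc, community$atom_excess, params)
    ## taxa x fraction band-mass matrix, truncated + renormalised in range
    p <- t(vapply(centre, function(mu) {
        pr <- stats::pnorm(upper, mu, params@band_sigma) -
            stats::pnorm(lower, mu, params@band_sigma)
        tot <- sum(pr)
        if (tot <= 0) {   # band centred far outside: put all mass at edge
            pr <- numeric(n)
            pr[if (mu <= params@density_min) n else 1] <- 1
            pr
        } else pr / tot
    }, numeric(n)))
    ## uniform background smear (unlabelled-DNA background in real gradients)
    bg <- params@background
    p <- (1 - bg) * p + bg / n
    mass <- p * (total_dna_ng * community$rel_abundance)
    frac_mass <- colSums(mass)

    set.seed(as.integer(seed %% 2147483647))
    counts <- matrix(0L, nrow = nrow(community), ncol = n,
                     dimnames = list(community$id, NULL))
    sizes <- round(depth * frac_mass / total_dna_ng)
    for (k in seq_len(n)) {
        if (sizes[k] > 0 && frac_mass[k] > 0)
            counts[, k] <- stats::rmultinom(1, sizes[k],
                                            mass[, k] / frac_mass[k])[, 1]
    }

    ## order densest first (fraction 1 = densest)
    ord <- order(mid, decreasing = TRUE)
    ri <- (mid + params@ri_intercept) / params@ri_slope
    FractionTable(counts = counts[, ord, drop = FALSE],
                  fraction = seq_len(n),
                  refractive_index = ri[ord],
                  density_g_ml = mid[ord],
                  dna_ng = frac_mass[ord],
                  vial_id = vial_id, substrate = substrate,
                  isotope = isotope, replicate = replicate,
                  labelled_taxa = community$id[community$atom_excess > 0])
}

#' Simulate a full SIP incubation experiment
#'
#' Produces one [FractionTable-class] per substrate x isotope x replicate
#' vial.  In \eqn{^{12}}C vials every taxon's atom excess is forced to 0; in
#' \eqn{^{13}}C vials only taxa whose `consumes` field includes the vial's
#' substrate keep their atom excess.  Replicate vials differ only by their
#' RNG stream, derived deterministically from (seed, substrate, isotope,
#' replicate).
#'
#' @param community community profile data.frame.
#' @param design A [SIPDesign-class].
#' @param params A [GradientParams-class].
#' @param total_dna_ng DNA mass per gradient, ng.
#' @return A [SIPDataset-class] named `substrate.isotope.rN`.
#' @examples
#' cm <- simulateCommunity(seed = 1)
#' ds <- simulateExperiment(cm, sipDesign(depth = 1e4, seed = 1))
#' names(ds)
#' @export
simulateExperiment <- function(community, design = sipDesign(),
                               params = gradientParams(),
                               total_dna_ng = 500) {
    .checkCommunity(community)
    flagged <- unique(unlist(strsplit(community$consumes[
        nzchar(community$consumes)], ";", fixed = TRUE)))
    unknown <- setdiff(flagged, design@substrates$name)
    if (length(unknown))
        stop("community flags consumers of substrate(s) absent from the ",
             "design: ", paste(unknown, collapse = ", "))
    vials <- list()
    for (si in seq_len(nrow(design@substrates))) {
        sub <- design@substrates$name[si]
        consumes_sub <- vapply(strsplit(community$consumes, ";", fixed = TRUE),
                               function(x) sub %in% x, logical(1))
        for (ii in seq_along(design@isotopes)) {
            iso <- design@isotopes[ii]
            eff <- community
            if (iso == "12C") {
                eff$atom_excess <- 0
            } else {
                eff$atom_excess[!consumes_sub] <- 0
            }
            for (r in seq_len(design@replicates)) {
                vid <- paste(sub, iso, paste0("r", r), sep = ".")
                vials[[vid]] <- simulateFractions(
                    eff, params = params, depth = design@depth,
                    total_dna_ng = total_dna_ng,
                    seed = .vialSeed(design@seed, si, ii, r),
                    vial_id = vid, substrate = sub, isotope = iso,
                    replicate = r)
            }
        }
    }
    out <- new("SIPDataset", SimpleList(vials))
    metadata(out) <- list(community = community, design = design,
                          params = params)
    out
}

#' Simulate a headspace gas consumption time series
#'
#' Expected concentration declines linearly with the consumption rate
#' (single initial gas charge, no replenishment), floored at zero; Gaussian
#' measurement noise is then added and the measurements clipped at zero.
#'
#' @param initial_pct initial headspace concentration, % v/v.
#' @param rate_umol_per_day gas consumption rate, umol/day.
#' @param headspace_ml headspace volume, ml.
#' @param days numeric vector of sampling times, days.
#' @param noise_sd Gaussian measurement noise on the %% scale.
#' @param seed integer seed.
#' @param vial_id,substrate,n_carbons series annotation.
#' @param sample_g,temperature_K,pressure_kPa passed to the series.
#' @return A [HeadspaceSeries-class].
#' @examples
#' simulateHeadspace(1, 2, 100, days = 0:10, noise_sd = 0)
#' @export
simulateHeadspace <- function(initial_pct = 1, rate_umol_per_day = 2,
                              headspace_ml = 100, days = 0:21,
                              noise_sd = 0.02, seed = 1L,
                              vial_id = "vial", substrate = "propane",
                              n_carbons = 3L, sample_g = 2,
                              temperature_K = 298.15,
                              pressure_kPa = 101.325) {
    if (initial_pct < 0)
        stop("initial_pct must be >= 0")
    if (rate_umol_per_day < 0)
        stop("rate_umol_per_day must be >= 0")
    n0 <- headspaceMicromoles(initial_pct, headspace_ml, temperature_K,
                              pressure_kPa)
    n_t <- pmax(0, n0 - rate_umol_per_day * days)
    pct <- if (n0 > 0) initial_pct * n_t / n0 else rep(0, length(days))
    if (noise_sd > 0) {
        set.seed(as.integer(seed %% 2147483647))
        pct <- pmax(0, pct + stats::rnorm(length(pct), 0, noise_sd))
    }
    headspaceSeries(vial_id = vial_id, substrate = substrate,
                    n_carbons = n_carbons, times = as.numeric(days),
                    pct_v_v = pct, headspace_ml = headspace_ml,
                    sample_g = sample_g, temperature_K = temperature_K,
                    pressure_kPa = pressure_kPa)
}
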