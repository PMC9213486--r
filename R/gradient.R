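## Refractive-index to buoyant-density conversion and heavy/light pooling.

#' Convert refractive index to buoyant density
#'
#' Affine conversion density = slope * RI - intercept.  Default coefficients
#' (10.9276, 13.593) follow the standard CsCl refractometer calibration;
#' both are temperature-specific and configurable.  Readings outside the
#' plausible CsCl range \[1.3, 1.5\] trigger a warning but are still
#' converted.
#'
#' @param ri refractive index (vectorised).
#' @param slope,intercept conversion coefficients.
#' @return Buoyant density, g/ml.
#' @examples
#' densityFromRI(1.4040)   # 1.74935
#' @export
densityFromRI <- function(ri, slope = 10.9276, intercept = 13.593) {
    if (any(ri < 1.3 | ri > 1.5))
        warning("refractive index outside the plausible CsCl range [1.3, 1.5]")
    slope * ri - intercept
}

#' Convert buoyant density to refractive index
#'
#' Exact inverse of [densityFromRI()].
#'
#' @param density buoyant density, g/ml (vectorised).
#' @param slope,intercept conversion coefficients.
#' @return Refractive index.
#' @export
riFromDensity <- function(density, slope = 10.9276, intercept = 13.593) {
    (density + intercept) / slope
}

#' Pool gradient fractions into heavy and light DNA windows
#'
#' A fraction is pooled into the heavy (light) pool iff its buoyant density
#' lies inside the closed heavy (light) window; fractions between or outside
#' the windows are discarded.  Counts are summed per taxon.  A vial with an
#' empty heavy or light pool is flagged unusable rather than silently
#' dropped.
#'
#' @param fractions A [FractionTable-class], or a data.frame with columns
#'   `density_g_ml` plus one count column per taxon.
#' @param windows A [PoolWindows-class].
#' @return A list with elements `heavy_counts`, `light_counts` (named
#'   per-taxon sums), `heavy_n`, `light_n` (fractions pooled), `usable`
#'   (logical) and `status` (character).
#' @examples
#' cm <- simulateCommunity(seed = 1)
#' ft <- simulateFractions(cm, depth = 1e4, seed = 1)
#' pp <- poolFractions(ft)
#' pp$heavy_n; pp$light_n
#' @export
poolFractions <- function(fractions, windows = poolWindows()) {
    if (is(fractions, "FractionTable")) {
        dens <- colData(fractions)$density_g_ml
        counts <- assay(fractions, "counts")
    } else {
        dens <- fractions$density_g_ml
        cc <- setdiff(names(fractions),
                      c("vial_id", "fraction", "refractive_index",
                        "density_g_ml", "dna_ng"))
        counts <- t(as.matrix(fractions[, cc, drop = FALSE]))
    }
    in_heavy <- dens >= windows@heavy[1] & dens <= windows@heavy[2]
    in_light <- dens >= windows@light[1] & dens <= windows@light[2]
    heavy_counts <- rowSums(counts[, in_heavy, drop = FALSE])
    light_counts <- rowSums(counts[, in_light, drop = FALSE])
    usable <- sum(in_heavy) >= 1L && sum(in_light) >= 1L
    list(heavy_counts = heavy_counts, light_counts = light_counts,
         heavy_n = sum(in_heavy), light_n = sum(in_light),
         usable = usable,
         status = if (usable) "ok" else "unusable: empty heavy or light pool")
}

#' Density profile of a gradient
#'
#' Table of DNA mass per fraction against buoyant density, sorted densest
#' first — the curve plotted to verify band separation in a SIP gradient.
#'
#' @param fractions A [FractionTable-class] or a data.frame with columns
#'   `density_g_ml` and `dna_ng`.
#' @return data.frame with columns `density_g_ml` and `dna_ng`, sorted by
#'   decreasing density.
#' @export
densityProfile <- function(fractions) {
    if (is(fractions, "FractionTable")) {
        df <- data.frame(density_g_ml = colData(fractions)$density_g_ml,
                         dna_ng = colData(fractions)$dna_ng)
    } else {
        df <- data.frame(density_g_ml = fractions$density_g_ml,
                         dna_ng = fractions$dna_ng)
    }
    if (nrow(df) < 2L)
        stop("need at least 2 fractions for a density profile")
    df[order(df$density_g_ml, decreasing = TRUE), , drop = FALSE]
}
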