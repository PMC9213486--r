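## Headspace gas accounting: % v/v -> umol -> umol C/g, harvest detection
## and consumption rates.

.R_GAS <- 8.314462618   # J / (mol K)

#' Micromoles of gas in a headspace at a given concentration
#'
#' Ideal-gas conversion: n = P * (pct/100 * V) / (R * T).  Dissolved-gas
#' partitioning is ignored (documented approximation).
#'
#' @param pct headspace concentration, % v/v (vectorised).
#' @param headspace_ml headspace volume, ml.
#' @param temperature_K temperature, K (default 298.15, i.e. 25 degC).
#' @param pressure_kPa pressure, kPa (default 101.325).
#' @return Micromoles of gas.
#' @examples
#' headspaceMicromoles(1, 100)   # ~40.88 umol
#' @export
headspaceMicromoles <- function(pct, headspace_ml,
                                temperature_K = 298.15,
                                pressure_kPa = 101.325) {
    if (headspace_ml <= 0)
        stop("headspace_ml must be > 0")
    if (any(pct < 0 | pct > 100))
        stop("pct must lie in [0, 100]")
    ## kPa * ml / (R * T) gives mmol * 1e-3; scale to umol
    1000 * pressure_kPa * (pct / 100) * headspace_ml /
        (.R_GAS * temperature_K)
}

#' Convert micromoles of alkane to micromoles of carbon
#'
#' @param umol_alkane micromoles of gas.
#' @param n_carbons carbon atoms per molecule (>= 1).
#' @return Micromoles of carbon.
#' @examples
#' carbonMicromoles(40.88, 3)   # propane
#' @export
carbonMicromoles <- function(umol_alkane, n_carbons) {
    if (any(n_carbons < 1))
        stop("n_carbons must be >= 1")
    umol_alkane * n_carbons
}

#' Cumulative substrate carbon consumed per gram of sample
#'
#' consumed(t) = (n(t0) - n(t)) * n_carbons / sample_g, with negative
#' interim excursions (measurement noise) clipped at the running maximum so
#' the series is non-decreasing.
#'
#' @param series A [HeadspaceSeries-class].
#' @return Numeric vector, umol C per g at each time point.
#' @export
cumulativeConsumption <- function(series) {
    if (length(series@times) < 2L)
        stop("need at least two time points")
    n_t <- headspaceMicromoles(series@pct_v_v, series@headspace_ml,
                               series@temperature_K, series@pressure_kPa)
    consumed <- carbonMicromoles(n_t[1] - n_t, series@n_carbons) /
        series@sample_g
    cummax(pmax(consumed, 0))
}

#' Earliest time a consumption target is reached
#'
#' @param series A [HeadspaceSeries-class].
#' @param target_umolC_per_g consumption target, umol C per g (> 0 for a
#'   harvest rule; 0 returns the first time point).
#' @return list with `vial_id`, `target_umolC_per_g` and `time_reached`
#'   (days, or NA if never reached).
#' @examples
#' hs <- simulateHeadspace(1, 4, 100, days = 0:30, noise_sd = 0)
#' harvestTime(hs, 50)
#' @export
harvestTime <- function(series, target_umolC_per_g) {
    if (target_umolC_per_g < 0)
        stop("target must be >= 0")
    cum <- cumulativeConsumption(series)
    hit <- which(cum >= target_umolC_per_g)
    list(vial_id = series@vial_id,
         target_umolC_per_g = target_umolC_per_g,
         time_reached = if (length(hit)) series@times[hit[1]] else NA_real_)
}

#' Substrate consumption rate of one or more replicate vials
#'
#' Per vial, fits ordinary least squares to cumulative consumption versus
#' time over the declining phase — from the start until the substrate first
#' falls below 5% of its initial concentration (cutoff configurable) — and
#' reports the slope.  Across vials the replicate mean and standard
#' deviation are returned.
#'
#' @param series A [HeadspaceSeries-class] or list of them (replicates).
#' @param depletion_cutoff fraction of the initial concentration below which
#'   the declining phase ends (default 0.05).
#' @return list with `rates` (per-vial umol C/g/day), `mean` and `sd`.
#' @examples
#' hs <- simulateHeadspace(1, 4, 100, days = 0:30, noise_sd = 0)
#' consumptionRate(hs)$mean
#' @export
consumptionRate <- function(series, depletion_cutoff = 0.05) {
    if (is(series, "HeadspaceSeries"))
        series <- list(series)
    rates <- vapply(series, function(s) {
        if (length(s@times) < 2L)
            stop("need at least two time points")
        cum <- cumulativeConsumption(s)
        init <- s@pct_v_v[1]
        below <- which(s@pct_v_v < depletion_cutoff * init)
        last <- if (length(below)) max(2L, below[1]) else length(s@times)
        idx <- seq_len(last)
        unname(stats::coef(stats::lm(cum[idx] ~ s@times[idx]))[2])
    }, numeric(1))
    names(rates) <- vapply(series, function(s) s@vial_id, character(1))
    list(rates = rates, mean = mean(rates),
         sd = if (length(rates) > 1L) stats::sd(rates) else 0)
}
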