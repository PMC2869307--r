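#' Inter-origin spacing sampler
#'
#' Returns a sampler closure emulating the measured inter-origin distance
#' distribution of budding yeast early origins (mean 46 kb).  The default
#' gamma family is positive and right-skewed; nonpositive draws (possible
#' only for other families) are resampled.
#'
#' @param meanKb mean spacing in kb (default 46).
#' @param cv coefficient of variation (default 0.55).
#' @param family "gamma", "lognormal" or "constant".
#' @return function(n) returning n positive spacings in kb.
#' @export
spacingSampler <- function(meanKb = 46, cv = 0.55,
                           family = c("gamma", "lognormal", "constant")) {
    stopifnot(meanKb > 0, cv >= 0)
    family <- match.arg(family)
    if (family == "constant" || cv == 0)
        return(function(n) rep(meanKb, n))
    if (family == "gamma") {
        shape <- 1 / cv^2
        fun <- function(n) rgamma(n, shape = shape, scale = meanKb / shape)
    } else {
        s2 <- log(1 + cv^2)
        fun <- function(n) stats::rlnorm(n, log(meanKb) - s2 / 2, sqrt(s2))
    }
    function(n) {
        x <- fun(n)
        while (any(bad <- x <= 0)) x[bad] <- fun(sum(bad))
        x
    }
}

#' Place origins on a linear chromosome
#'
#' Draws n - 1 i.i.d. spacings from the sampler and accumulates them from
#' position 0.
#'
#' @param sampler spacing sampler from [spacingSampler()].
#' @param n number of origins (>= 1).
#' @param seed RNG seed for reproducibility.
#' @return numeric vector of n strictly increasing positions in kb.
#' @export
placeOrigins <- function(sampler = spacingSampler(), n = 190, seed = NULL) {
    stopifnot(n >= 1)
    if (!is.null(seed)) set.seed(seed)
    c(0, cumsum(sampler(n - 1)))
}

#' Assign firing times by sampling the firing-rate density
#'
#' Inverse-CDF sampling of the (normalized) firing density on its time grid,
#' with linear interpolation within grid cells.
#'
#' @param profile FiringProfile (must have positive total mass).
#' @param n number of draws.
#' @param seed RNG seed.
#' @param units "min" (default) or "s".
#' @return numeric vector of n firing times.
#' @export
assignFiringTimes <- function(profile, n, seed = NULL,
                              units = c("min", "s")) {
    units <- match.arg(units)
    t <- profile@time; f <- profile@f
    cdf <- c(0, cumsum(diff(t) * (head(f, -1) + tail(f, -1)) / 2))
    if (max(cdf) <= 0) stop("zero-mass firing density")
    cdf <- cdf / max(cdf)
    if (!is.null(seed)) set.seed(seed)
    u <- runif(n)
    ## generalized inverse of the piecewise-linear CDF: keep only points
    ## that start or end a rise, so flat (zero-density) stretches are never
    ## interpolated across; tiny nudges make the kept values strictly
    ## increasing for approx()
    rise <- diff(cdf) > 0
    keep <- c(rise, FALSE) | c(FALSE, rise)
    ck <- cdf[keep] + seq_len(sum(keep)) * 1e-12
    times <- approx(ck, t[keep], xout = u, rule = 2)$y
    if (units == "min") times / 60 else times
}

#' Compute replicon geometry from origin positions and firing times
#'
#' An origin is passively replicated if an external fork reaches its position
#' strictly before its own firing time.  Between adjacent fired origins at
#' distance d with firing times t1 <= t2, forks meet at (d + v (t2 - t1))/2
#' from the earlier origin; the outermost fired origins replicate to the
#' chromosome ends.
#'
#' @param positions origin positions in kb, strictly increasing.
#' @param times firing times in minutes.
#' @param v fork speed in kb/min (default 1.5).
#' @param chromLength chromosome length in kb (default: rightmost origin).
#' @return A [RepliconMap-class] object.
#' @export
computeReplicons <- function(positions, times, v = 1.5,
                             chromLength = NULL) {
    stopifnot(length(positions) == length(times), v > 0)
    n <- length(positions)
    if (is.null(chromLength)) chromLength <- max(positions)
    ## passive test against all other origins is equivalent to the test
    ## against fired origins only (triangle inequality)
    passive <- vapply(seq_len(n), function(i) {
        if (n == 1) return(FALSE)
        d <- abs(positions[-i] - positions[i])
        any(times[-i] + d / v < times[i])
    }, logical(1))
    fired <- which(!passive)
    if (!length(fired)) stop("no origin fires")
    fp <- positions[fired]; ft <- times[fired]; k <- length(fired)
    bounds <- matrix(0, n, 2)
    sizes <- numeric(n)
    ## boundaries between consecutive fired origins
    innerB <- numeric(0)
    if (k > 1) {
        d <- diff(fp); dt <- ft[-1] - ft[-k]
        innerB <- fp[-k] + pmin(pmax((d + v * dt) / 2, 0), d)
    }
    lb <- c(0, innerB); rb <- c(innerB, chromLength)
    bounds[fired, 1] <- lb; bounds[fired, 2] <- rb
    sizes[fired] <- rb - lb
    ## completion: inner meetings plus arrivals at the two chromosome ends
    meet <- if (k > 1) (ft[-1] + ft[-k]) / 2 + diff(fp) / (2 * v) else numeric(0)
    endL <- ft[1] + (fp[1] - 0) / v
    endR <- ft[k] + (chromLength - fp[k]) / v
    sphase <- max(c(meet, endL, endR)) - min(ft)
    new("RepliconMap", chromLength = chromLength, positions = positions,
        times = times, forkSpeed = v,
        status = ifelse(passive, "passive", "fired"),
        sizes = sizes, boundaries = bounds, sPhase = sphase)
}

#' Fraction of passively replicated origins
#' @param positions,times,v as in [computeReplicons()].
#' @export
passiveFraction <- function(positions, times, v = 1.5) {
    map <- computeReplicons(positions, times, v)
    mean(map@status == "passive")
}

#' S-phase length of a replicon map (minutes)
#' @param map RepliconMap.
#' @export
sPhaseLength <- function(map) map@sPhase

#' Replicon sizes (kb), optionally only for fired origins
#' @param map RepliconMap.
#' @param firedOnly drop passive origins (default TRUE).
#' @export
repliconSizes <- function(map, firedOnly = TRUE) {
    if (firedOnly) map@sizes[map@status == "fired"] else map@sizes
}

#' Summarize a replicon map
#' @param map RepliconMap.
#' @return list with origin counts, passive fraction, size quantiles and
#'   S-phase length.
#' @export
repliconSummary <- function(map) {
    sz <- repliconSizes(map)
    list(nOrigins = length(map@positions),
         nFired = sum(map@status == "fired"),
         passiveFraction = mean(map@status == "passive"),
         meanSizeKb = mean(sz),
         sizeQuantilesKb = stats::quantile(sz, c(0.05, 0.25, 0.5, 0.75, 0.95)),
         maxSizeKb = max(sz),
         sPhaseMin = map@sPhase)
}

#' Export a replicon map as a BED-like data.frame
#' @param map RepliconMap.
#' @param chrom chromosome name (default "chrSim").
#' @export
repliconTable <- function(map, chrom = "chrSim") {
    data.frame(chrom = chrom,
               start = map@boundaries[, 1], end = map@boundaries[, 2],
               origin_id = seq_along(map@positions),
               position_kb = map@positions,
               firing_time_min = map@times, status = map@status,
               size_kb = map@sizes, stringsAsFactors = FALSE)
}
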