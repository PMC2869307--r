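#' Firing-rate profile of a trajectory
#'
#' The firing rate f(t) is the total instantaneous flux of origins into the
#' replicating states S9 and S9P, including any refiring flux through the
#' relicensing channel.
#'
#' @param traj Trajectory.
#' @param M number of origins (default: the model's M).
#' @return A [FiringProfile-class] object.
#' @export
firingProfile <- function(traj, M = NULL) {
    if (is.null(M)) M <- traj@model@options$M
    new("FiringProfile", time = traj@time, f = traj@fire, M = M)
}

#' Construct a firing profile from an arbitrary density
#' @param time time grid, seconds.
#' @param f firing-rate density per origin, 1/s.
#' @param M number of origins.
#' @export
firingProfileFromDensity <- function(time, f, M = 190)
    new("FiringProfile", time = time, f = f, M = M)

#' Expected number of origin-firing events
#'
#' N = M * integral of f over the horizon (trapezoid rule).  Includes
#' refiring events when the relicensing channel is open.
#'
#' @param profile FiringProfile.
#' @return numeric N.
#' @export
totalFirings <- function(profile)
    profile@M * .trapz(profile@time, profile@f)

#' Mean time to origin firing (tau)
#'
#' First moment of the firing-rate density, measured from exit from mitosis.
#'
#' @param profile FiringProfile.
#' @param units "s" or "min".
#' @return tau; NA with a warning if no firing occurred.
#' @export
meanFiringTime <- function(profile, units = c("s", "min")) {
    units <- match.arg(units)
    m0 <- .trapz(profile@time, profile@f)
    if (m0 <= 0) { warning("zero total firing; tau undefined"); return(NA_real_) }
    tau <- .trapz(profile@time, profile@time * profile@f) / m0
    if (units == "min") tau / 60 else tau
}

#' Duration of origin firing (Delta)
#'
#' Twice the standard deviation of the firing-rate density: the mean time
#' between the firing of two randomly chosen origins, i.e. the (inverse)
#' temporal coherence of origin activation.
#'
#' @param profile FiringProfile.
#' @param units "s" or "min".
#' @return Delta; NA with a warning if no firing occurred.
#' @export
firingDuration <- function(profile, units = c("s", "min")) {
    units <- match.arg(units)
    m0 <- .trapz(profile@time, profile@f)
    if (m0 <= 0) { warning("zero total firing; Delta undefined"); return(NA_real_) }
    m1 <- .trapz(profile@time, profile@time * profile@f) / m0
    m2 <- .trapz(profile@time, profile@time^2 * profile@f) / m0
    v <- m2 - m1^2
    if (v < 0) {
        if (v < -1e-8 * m2) stop("negative variance in firing profile")
        v <- 0
    }
    d <- 2 * sqrt(v)
    if (units == "min") d / 60 else d
}

#' Mass of the firing density lost to horizon truncation
#'
#' Ratio of the terminal density value to the peak; large values indicate
#' that the moments are computed on a truncated profile.
#'
#' @param profile FiringProfile.
#' @export
truncatedMass <- function(profile) {
    pk <- max(profile@f)
    if (pk <= 0) return(0)
    profile@f[length(profile@f)] / pk
}

#' Average number of rereplicating origins (rho)
#'
#' Runs the model twice, once as configured and once with the relicensing
#' gate closed (k16 = 0), and returns rho = N - N0 together with both runs'
#' summary statistics.
#'
#' @param pools ProteinPool.
#' @param params ParameterSet.
#' @param horizon,dt,rtol,atol passed to [simulateModel()].
#' @param ... structural options passed to [buildModel()].
#' @return list with rho, N, N0 and the two FiringProfiles.
#' @export
rereplicationCount <- function(pools = defaultProteinPool(),
                               params = defaultParameterSet(),
                               horizon = 10800, dt = 20,
                               rtol = 1e-8, atol = 1e-12, ...) {
    m1 <- buildModel(pools = pools, params = params, ...)
    m0 <- buildModel(pools = pools,
                     params = setParamValues(params, c(k16 = 0)), ...)
    t1 <- simulateModel(m1, horizon = horizon, dt = dt, rtol = rtol,
                        atol = atol)
    t0 <- simulateModel(m0, horizon = horizon, dt = dt, rtol = rtol,
                        atol = atol)
    p1 <- firingProfile(t1); p0 <- firingProfile(t0)
    N <- totalFirings(p1); N0 <- totalFirings(p0)
    rho <- N - N0
    if (rho < -1e-3 * max(N, 1))
        stop("negative rereplication count beyond tolerance: rho = ", rho)
    list(rho = max(rho, 0), N = N, N0 = N0, profile = p1, profile0 = p0)
}

#' Flat metrics record of a simulated trajectory
#'
#' Uses the exact cumulative-flux and moment accumulators integrated along
#' with the state (not grid quadrature), so sharp firing pulses narrower
#' than the output grid are measured correctly.
#'
#' @param traj Trajectory (run with the configured k16).
#' @param traj0 optional paired Trajectory with k16 = 0 (for rho).
#' @return list with N, N0, rho, tau_min, Delta_min, truncated_mass.
#' @export
firingMetrics <- function(traj, traj0 = NULL) {
    M <- traj@model@options$M
    last <- nrow(traj@states)
    m0 <- unname(traj@states[last, "cumFire"])
    N <- M * m0
    N0 <- if (is.null(traj0)) NA_real_ else
        traj0@model@options$M *
            unname(traj0@states[nrow(traj0@states), "cumFire"])
    fired <- m0 > 1e-9
    tau <- delta <- NA_real_
    if (fired) {
        m1 <- unname(traj@states[last, "cumFireT"]) / m0
        m2 <- unname(traj@states[last, "cumFireT2"]) / m0
        tau <- m1 / 60
        delta <- 2 * sqrt(max(m2 - m1^2, 0)) / 60
    }
    list(N = N, N0 = N0,
         rho = if (is.null(traj0)) NA_real_ else max(N - N0, 0),
         tau_min = tau, Delta_min = delta,
         truncated_mass = truncatedMass(firingProfile(traj)))
}
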