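#' Integrate the mean-field balance equations
#'
#' Solves the stiff ODE system with the compiled right-hand side using
#' [deSolve::ode] (lsoda).  Time is in seconds with t = 0 at exit from
#' mitosis; the initial condition has all origins in S0 and S-Cdk bound to
#' Sic1.
#'
#' @param model ReplicationModel from [buildModel()].
#' @param horizon integration horizon in seconds (default 3 h).
#' @param dt output grid spacing in seconds (default 20 s).
#' @param rtol,atol solver tolerances (defaults 1e-8 and 1e-12 M).
#' @param maxsteps maximal internal solver steps between output points.
#' @return A [Trajectory-class] object.
#' @export
simulateModel <- function(model, horizon = 10800, dt = 20,
                          rtol = 1e-8, atol = 1e-12, maxsteps = 20000) {
    stopifnot(is(model, "ReplicationModel"))
    times <- seq(0, horizon, by = dt)
    out <- deSolve::ode(y = unname(model@y0), times = times,
                        func = "replinet_derivs", parms = unname(model@parms),
                        dllname = "RepliNet", initfunc = "replinet_initmod",
                        nout = 2, outnames = c("fire", "g1"),
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = maxsteps)
    istate <- attr(out, "istate")[1]
    if ((!is.null(istate) && istate < 0) || nrow(out) < length(times))
        stop("integration failed (istate = ", istate, ") near t = ",
             signif(out[nrow(out), 1], 4), " s")
    states <- out[, 2:(.NSTATE + 1), drop = FALSE]
    colnames(states) <- .stateNames
    new("Trajectory", time = out[, 1], states = states,
        fire = pmax(out[, "fire"], 0), model = model)
}

#' Time grid of a trajectory (seconds)
#' @param traj Trajectory.
#' @export
trajTime <- function(traj) traj@time

#' Origin-state occupancy fractions over time
#' @param traj Trajectory.
#' @return matrix, 20 columns S0..S9, S0P..S9P.
#' @export
originStates <- function(traj) traj@states[, .originStateNames, drop = FALSE]

#' Time course of one or more state variables
#' @param traj Trajectory.
#' @param name state names (see colnames of the states matrix).
#' @export
speciesState <- function(traj, name) {
    if (length(miss <- setdiff(name, .stateNames)))
        stop("unknown state: ", paste(miss, collapse = ", "))
    traj@states[, name, drop = length(name) > 1]
}

#' Instantaneous per-origin firing rate f(t)
#' @param traj Trajectory.
#' @return numeric, 1/s, same length as the time grid.
#' @export
firingFlux <- function(traj) traj@fire

## trapezoid integral
.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Consistency diagnostics of a trajectory
#'
#' Checks the conservation laws of the network: origin-state occupancies sum
#' to one, total Sld2/Sld3/Dpb11/S-Cdk mass is conserved across phospho-forms
#' and complexes, and Cdc6/Cdt1/Mcm/Sic1 are conserved once the cumulative
#' degradation/export sinks are included.  Origin-bound amounts are counted
#' with the molar origin concentration.
#'
#' @param traj Trajectory.
#' @return named numeric vector of maximal absolute conservation errors,
#'   relative to the initial totals (occupancy error is absolute).
#' @export
conservationErrors <- function(traj) {
    st <- traj@states
    p <- traj@model@parms
    Cori <- p[["Cori"]]
    n3 <- p[["nSld3"]]
    occ <- rowSums(st[, .originStateNames])
    relerr <- function(total) {
        t0 <- total[1]
        if (t0 <= 0) return(max(abs(total - t0)))
        max(abs(total - t0)) / t0
    }
    orig <- function(states) rowSums(st[, states, drop = FALSE]) * Cori
    ## origin-bound activator sits in S6/S7 (plus P layer)
    boundT <- orig(c("S6", "S7", "S6P", "S7P"))
    variant <- p[["bindVariant"]] > 0
    sld2 <- rowSums(st[, c(paste0("Sld2_", 0:8), "pSld2")]) +
        st[, "Dpb11pSld2"] + st[, "Activator"] +
        (if (variant) orig(c("S7", "S7P")) else boundT)
    sld3 <- rowSums(st[, paste0("Sld3_", 0:8)]) + st[, "Dpb11pSld3"] +
        st[, "Activator"] + boundT
    dpb <- st[, "Dpb11"] + st[, "Dpb11pSld2"] + st[, "Dpb11pSld3"] +
        st[, "Activator"] + boundT
    scdk <- st[, "SCdk"] + rowSums(st[, paste0("Sic1SCdk_", 0:8)])
    sic1 <- rowSums(st[, paste0("Sic1SCdk_", 0:8)]) +
        rowSums(st[, paste0("Sic1_", 0:8)]) + st[, "sinkSic1"]
    cdc6 <- st[, "Cdc6"] + st[, "sinkCdc6"] +
        orig(c("S1", "S2", "S1P"))
    cdt1 <- st[, "Cdt1"] + st[, "Cdt1Mcm"] + st[, "sinkCdt1"] +
        orig("S2")
    mcm <- st[, "Mcm"] + st[, "Cdt1Mcm"] + st[, "sinkMcm"] +
        st[, "seqMcm"] +
        orig(c(paste0("S", 2:9), paste0("S", 3:9, "P")))
    c(occupancy = max(abs(occ - 1)),
      Sld2 = relerr(sld2), Sld3 = relerr(sld3), Dpb11 = relerr(dpb),
      SCdk = relerr(scdk), Sic1 = relerr(sic1), Cdc6 = relerr(cdc6),
      Cdt1 = relerr(cdt1), Mcm = relerr(mcm))
}
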