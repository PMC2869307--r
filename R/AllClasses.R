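#' @import methods
#' @importFrom stats approx approxfun cor quantile rexp rgamma rlnorm runif
#'   sd setNames
#' @importFrom utils head tail
NULL

AVOGADRO <- 6.02214076e23

#' Kinetic parameter set for the replication-initiation network
#'
#' Holds one row per rate constant with its reaction kind, the network module
#' it belongs to, biochemically feasible bounds and an optimizable flag.
#' Bimolecular on-rates carry the name of their paired off-rate so that
#' dissociation constants Kd = k_off/k_on are always defined.
#'
#' @slot params data.frame with columns \code{name}, \code{kind}
#'   (binding, unbinding, catalytic, michaelis, degradation, export,
#'   relicensing), \code{value}, \code{unit}, \code{module} (licensing, scdk,
#'   activator, firing), \code{low}, \code{high}, \code{optimizable},
#'   \code{pair} (off-rate partner for binding entries, else NA).
#' @export
setClass("ParameterSet", representation(params = "data.frame"))

setValidity("ParameterSet", function(object) {
    pr <- object@params
    need <- c("name", "kind", "value", "unit", "module", "low", "high",
              "optimizable", "pair")
    if (!all(need %in% names(pr)))
        return(paste("missing columns:",
                     paste(setdiff(need, names(pr)), collapse = ", ")))
    if (anyDuplicated(pr$name)) return("duplicated parameter names")
    ## sinks may be switched off (k16 = 0, non-degradable mutants); binding
    ## and catalytic constants must stay positive
    nonneg <- pr$kind %in% c("degradation", "export", "relicensing")
    if (any(pr$value[!nonneg] <= 0)) return("rate constants must be > 0")
    if (any(pr$value < 0)) return("negative rate constant")
    opt <- pr$optimizable & !(nonneg & pr$value == 0)
    if (any(opt & (pr$value < pr$low | pr$value > pr$high)))
        return("optimizable value outside its feasible bounds")
    onr <- pr[pr$kind == "binding", ]
    if (!all(onr$pair %in% pr$name[pr$kind == "unbinding"]))
        return("binding rate without a paired unbinding rate")
    TRUE
})

#' Protein abundances per nucleus
#'
#' Molecule counts per nucleus together with the nuclear volume used for
#' count/concentration conversion (1 molecule in 2e-15 L is about 0.83 nM).
#'
#' @slot counts named numeric vector of molecule counts.
#' @slot volume nuclear volume in litres.
#' @export
setClass("ProteinPool",
         representation(counts = "numeric", volume = "numeric"))

setValidity("ProteinPool", function(object) {
    if (length(object@volume) != 1L || object@volume <= 0)
        return("volume must be a single positive number")
    if (is.null(names(object@counts))) return("counts must be named")
    if (any(!is.finite(object@counts)) || any(object@counts < 0))
        return("counts must be finite and >= 0")
    TRUE
})

#' G1-Cdk input time course
#'
#' Hill-in-time sigmoid: activity(t) = amplitude * t^h / (t^h + midpoint^h)
#' with h = midpoint/sigma, so that sigma is the time scale over which the
#' kinase switches on around the midpoint.
#'
#' @slot amplitude maximal activity, molecule counts.
#' @slot midpoint activation midpoint, seconds.
#' @slot sigma activation sharpness, seconds.
#' @export
setClass("G1CdkInput",
         representation(amplitude = "numeric", midpoint = "numeric",
                        sigma = "numeric"))

setValidity("G1CdkInput", function(object) {
    if (object@amplitude < 0) return("amplitude must be >= 0")
    if (object@midpoint <= 0 || object@sigma <= 0)
        return("midpoint and sigma must be > 0")
    TRUE
})

#' Assembled replication-initiation model
#'
#' Produced by [buildModel()]; bundles pools, parameters, structural options,
#' the packed parameter vector and initial condition passed to the compiled
#' right-hand side, and the enumerated reaction list.
#'
#' @slot pools ProteinPool.
#' @slot params ParameterSet.
#' @slot options list of structural options (see [buildModel()]).
#' @slot g1 G1CdkInput.
#' @slot parms packed numeric parameter vector for the C integrand.
#' @slot y0 named initial state.
#' @slot reactions data.frame enumerating the origin-state reactions.
#' @export
setClass("ReplicationModel",
         representation(pools = "ProteinPool", params = "ParameterSet",
                        options = "list", g1 = "G1CdkInput",
                        parms = "numeric", y0 = "numeric",
                        reactions = "data.frame"))

#' Simulated trajectory of the network
#'
#' @slot time time grid, seconds (t = 0 at exit from mitosis).
#' @slot states matrix, one column per state variable (origin-state fractions,
#'   free-species concentrations in molar, cumulative accumulators).
#' @slot fire instantaneous per-origin firing rate f(t), 1/s.
#' @slot model the ReplicationModel that was integrated.
#' @export
setClass("Trajectory",
         representation(time = "numeric", states = "matrix",
                        fire = "numeric", model = "ReplicationModel"))

setValidity("Trajectory", function(object) {
    if (any(diff(object@time) <= 0)) return("time must be strictly increasing")
    if (nrow(object@states) != length(object@time))
        return("states/time dimension mismatch")
    TRUE
})

#' Origin firing-rate profile and derived statistics
#'
#' @slot time time grid, seconds.
#' @slot f firing-rate density per origin, 1/s.
#' @slot M number of origins the profile refers to.
#' @export
setClass("FiringProfile",
         representation(time = "numeric", f = "numeric", M = "numeric"))

setValidity("FiringProfile", function(object) {
    if (length(object@time) != length(object@f))
        return("time/f length mismatch")
    if (any(object@f < -1e-12)) return("firing rate must be nonnegative")
    if (object@M <= 0) return("M must be positive")
    TRUE
})

#' Collapsed random-sequential multisite phosphorylation chain
#'
#' Tracks the number of phosphorylated random sites j = 0..n plus, optionally,
#' a hierarchical final site (Thr84-like) that only becomes available once all
#' random sites are phosphorylated.  Per-site kinetics are identical, which
#' makes the collapsed representation exact.
#'
#' @slot nRandom number of symmetric random sites.
#' @slot finalSite logical; hierarchical final site present.
#' @slot kcat,Km per-site kinase turnover and Michaelis constant.
#' @slot kcatFinal,KmFinal kinetics of the final site.
#' @slot kp per-site dephosphorylation rate, 1/s.
#' @slot ctot total substrate concentration entering the saturation term.
#' @slot processive logical; single-encounter (processive) variant.
#' @export
setClass("PhosphoChain",
         representation(nRandom = "numeric", finalSite = "logical",
                        kcat = "numeric", Km = "numeric",
                        kcatFinal = "numeric", KmFinal = "numeric",
                        kp = "numeric", ctot = "numeric",
                        processive = "logical"))

#' Replicon geometry computed from origin positions and firing times
#'
#' @slot chromLength chromosome length, kb.
#' @slot positions origin positions, kb, strictly increasing.
#' @slot times firing times, minutes.
#' @slot forkSpeed fork speed, kb/min.
#' @slot status character, "fired" or "passive" per origin.
#' @slot sizes replicon sizes, kb (0 for passive origins).
#' @slot boundaries fork-meeting boundaries flanking each origin, kb.
#' @slot sPhase S-phase length, minutes.
#' @export
setClass("RepliconMap",
         representation(chromLength = "numeric", positions = "numeric",
                        times = "numeric", forkSpeed = "numeric",
                        status = "character", sizes = "numeric",
                        boundaries = "matrix", sPhase = "numeric"))

setValidity("RepliconMap", function(object) {
    if (any(diff(object@positions) <= 0))
        return("positions must be strictly increasing")
    if (length(object@times) != length(object@positions))
        return("times/positions length mismatch")
    fired <- object@status == "fired"
    if (abs(sum(object@sizes[fired]) - object@chromLength) > 1e-6)
        return("replicon sizes do not tile the chromosome")
    TRUE
})

#' Ensemble of admissible optimized parameter sets
#'
#' @slot members list of ParameterSet objects.
#' @slot metrics data.frame with N, N0, rho, tau_min, Delta_min per member.
#' @slot provenance list recording seeds and optimizer configuration.
#' @export
setClass("AdmissibleEnsemble",
         representation(members = "list", metrics = "data.frame",
                        provenance = "list"))

setMethod("show", "ParameterSet", function(object) {
    pr <- object@params
    cat("ParameterSet:", nrow(pr), "rate constants (",
        sum(pr$optimizable), "optimizable )\n")
    for (m in unique(pr$module))
        cat("  module", m, ":", sum(pr$module == m), "parameters\n")
})

setMethod("show", "ProteinPool", function(object) {
    cat("ProteinPool:", length(object@counts), "species, nuclear volume",
        format(object@volume, digits = 3), "L\n")
    print(object@counts)
})

setMethod("show", "ReplicationModel", function(object) {
    o <- object@options
    cat("ReplicationModel:", if (o$orcLayer) 20 else 10, "origin states;",
        "phosphosites Sic1/Sld2/Sld3 =", o$nSic1, "/", o$nSld2, "+Thr84 /",
        o$nSld3, "\n")
    cat("  binding order:", o$bindingOrder,
        if (o$constitutiveSld2 || o$constitutiveSld3)
            "; constitutive Sld2/Sld3" else "", "\n")
})

setMethod("show", "Trajectory", function(object) {
    cat("Trajectory:", length(object@time), "time points over",
        format(max(object@time) / 60, digits = 4), "min;",
        ncol(object@states), "state variables\n")
})

setMethod("show", "FiringProfile", function(object) {
    cat("FiringProfile over", format(max(object@time) / 60, digits = 4),
        "min, M =", object@M, "origins\n")
})

setMethod("show", "AdmissibleEnsemble", function(object) {
    cat("AdmissibleEnsemble:", length(object@members), "members\n")
    if (nrow(object@metrics))
        print(summary(object@metrics[, c("tau_min", "Delta_min", "N", "rho")]))
})
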