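## State-vector layout shared with src/replinet_rhs.c (1-based here).
.stateNames <- local({
    s <- c(paste0("S", 0:9), paste0("S", 0:9, "P"),
           "Cdc6", "Cdt1", "Mcm", "Cdt1Mcm", "Cdc45", "GINS", "Pol",
           "GINSPol", "Dpb11",
           paste0("Sld2_", 0:8), "pSld2",
           paste0("Sld3_", 0:8),
           "Dpb11pSld2", "Dpb11pSld3", "Activator", "SCdk",
           paste0("Sic1SCdk_", 0:8), paste0("Sic1_", 0:8),
           "sinkCdc6", "sinkCdt1", "sinkMcm", "sinkSic1",
           "seqMcm", "seqCdc45", "seqGINSPol",
           "cumFire", "cumRelicense", "cumFireT", "cumFireT2")
    s
})

.NSTATE <- length(.stateNames)   # 79

.originStateNames <- .stateNames[1:20]

.parmNames <- c("Cori", "g1Amp", "g1Mid", "g1Hill", "orcLayer", "clampPools",
                "constSld2", "constSld3", "nSic1", "nSld2", "nSld3",
                "bindVariant", "Pt", "Ddk",
                "kon6", "koff6", "konCM", "koffCM", "konL", "koffL", "kload",
                "Kavail", "kd6", "kexp",
                "kcatSic", "KmSic", "kpSic", "kdegSic", "konSC", "koffSC",
                "kcatMcm", "KmMcm", "kon45", "koff45", "konT", "koffT",
                "konGPo", "koffGPo", "krel", "kfire", "kcatOrc", "KmOrc",
                "k16",
                "kcat2", "Km2", "kcatT84", "KmT84", "kcat3", "Km3",
                "kcatP", "KmP",
                "konD2", "koffD2", "konD3", "koffD3", "konT2", "koffT2",
                "konT3", "koffT3", "konGP0", "koffGP0", "scdkTot")

.defaultOptions <- function() {
    list(orcLayer = TRUE, nSic1 = 6, nSld2 = 6, nSld3 = 2,
         constitutiveSld2 = FALSE, constitutiveSld3 = FALSE,
         bindingOrder = "solution", clampPools = FALSE, M = 190)
}

#' Assemble the replication-initiation model
#'
#' Translates a protein pool and a kinetic parameter set into the packed
#' parameter vector, initial condition and reaction list of the four-module
#' origin-activation network.  The default topology has 20 origin states:
#' the assembly chain S0 (ORC) -> S1 (+Cdc6) -> S2 (+Cdt1.Mcm) -> S3 (pre-RC)
#' -> S4 (Mcm phosphorylated) -> S5 (+Cdc45) -> S6 (+11-3-2) -> S7
#' (+GINS.Pol) -> S8 (activator released) -> S9 (fired), mirrored in an
#' ORC-phosphorylated layer in which Cdt1.Mcm loading is blocked.
#'
#' @param pools ProteinPool (all abundances must be nonnegative).
#' @param params ParameterSet (all rate constants must be present).
#' @param g1 G1CdkInput; defaults to [g1CdkInput()] with the amplitude taken
#'   from the pool's G1Cdk entry.
#' @param orcLayer include the ORC-phosphorylation layer (default TRUE).
#' @param nSic1,nSld2,nSld3 phosphosite counts: random sites of Sic1 (6),
#'   random sites of Sld2 before Thr84 (6), sites of Sld3 (2).  Maximum 8.
#' @param constitutiveSld2,constitutiveSld3 treat the protein as fully
#'   activated from t = 0 (phospho-chain bypassed).
#' @param bindingOrder "solution" (11-3-2 pre-assembles in solution) or
#'   "origin" (Dpb11.pSld3 docks first, pSld2 joins at the origin).
#' @param clampPools freeze all free-species concentrations (diagnostic use).
#' @param M number of origins represented (default 190), which sets the molar
#'   concentration equivalent of the origin complement.
#' @return A [ReplicationModel-class] object.
#' @export
buildModel <- function(pools = defaultProteinPool(),
                       params = defaultParameterSet(),
                       g1 = NULL, orcLayer = TRUE,
                       nSic1 = 6, nSld2 = 6, nSld3 = 2,
                       constitutiveSld2 = FALSE, constitutiveSld3 = FALSE,
                       bindingOrder = c("solution", "origin"),
                       clampPools = FALSE, M = 190) {
    stopifnot(is(pools, "ProteinPool"), is(params, "ParameterSet"))
    bindingOrder <- match.arg(bindingOrder)
    if (any(pools@counts < 0)) stop("negative protein abundance")
    if (nSic1 < 1 || nSic1 > 8) stop("nSic1 must be in 1..8")
    if (nSld2 < 0 || nSld2 > 8) stop("nSld2 must be in 0..8")
    if (nSld3 < 1 || nSld3 > 8) stop("nSld3 must be in 1..8")
    validObject(params); validObject(pools)

    needed <- setdiff(.parmNames,
                      c("Cori", "g1Amp", "g1Mid", "g1Hill", "orcLayer",
                        "clampPools", "constSld2", "constSld3", "nSic1",
                        "nSld2", "nSld3", "bindVariant", "Pt", "Ddk",
                        "scdkTot"))
    have <- params@params$name
    if (length(miss <- setdiff(needed, have)))
        stop("missing rate constant(s): ", paste(miss, collapse = ", "))

    if (is.null(g1))
        g1 <- g1CdkInput(amplitude = poolCount(pools, "G1Cdk"))
    vol <- pools@volume
    conc <- function(p) poolConcentration(pools, p)

    parms <- setNames(numeric(length(.parmNames)), .parmNames)
    parms[needed] <- paramValue(params, needed)
    parms["Cori"] <- countToMolar(M, vol)
    parms["g1Amp"] <- countToMolar(g1@amplitude, vol)
    parms["g1Mid"] <- g1@midpoint
    parms["g1Hill"] <- g1@midpoint / g1@sigma
    parms["orcLayer"] <- as.numeric(orcLayer)
    parms["clampPools"] <- as.numeric(clampPools)
    parms["constSld2"] <- as.numeric(constitutiveSld2)
    parms["constSld3"] <- as.numeric(constitutiveSld3)
    parms["nSic1"] <- nSic1
    parms["nSld2"] <- nSld2
    parms["nSld3"] <- nSld3
    parms["bindVariant"] <- as.numeric(bindingOrder == "origin")
    parms["Pt"] <- conc("Phosphatase")
    parms["Ddk"] <- conc("Ddk")
    parms["scdkTot"] <- max(conc("SCdk"), countToMolar(1, vol))

    y0 <- setNames(numeric(.NSTATE), .stateNames)
    y0["S0"] <- 1
    y0["Cdc6"] <- conc("Cdc6"); y0["Cdt1"] <- conc("Cdt1")
    y0["Mcm"] <- conc("Mcm");   y0["Cdc45"] <- conc("Cdc45")
    y0["GINS"] <- conc("GINS"); y0["Pol"] <- conc("Pol")
    y0["Dpb11"] <- conc("Dpb11")
    y0[if (constitutiveSld2) "pSld2" else "Sld2_0"] <- conc("Sld2")
    y0[if (constitutiveSld3) paste0("Sld3_", nSld3) else "Sld3_0"] <-
        conc("Sld3")
    ## S-Cdk starts fully inhibited by Sic1; excess of either goes free
    scdk <- conc("SCdk"); sic1 <- conc("Sic1")
    y0["Sic1SCdk_0"] <- min(scdk, sic1)
    y0["SCdk"] <- max(0, scdk - sic1)
    y0["Sic1_0"] <- max(0, sic1 - scdk)

    opts <- list(orcLayer = orcLayer, nSic1 = nSic1, nSld2 = nSld2,
                 nSld3 = nSld3, constitutiveSld2 = constitutiveSld2,
                 constitutiveSld3 = constitutiveSld3,
                 bindingOrder = bindingOrder, clampPools = clampPools, M = M)
    new("ReplicationModel", pools = pools, params = params, options = opts,
        g1 = g1, parms = parms, y0 = y0,
        reactions = .enumerateReactions(opts))
}

## Enumerate the origin-state conversion reactions for the chosen topology.
## Each row moves one origin from `from` to `to`; `consumes`/`releases` name
## free species bound or returned with stoichiometry one per origin.
.enumerateReactions <- function(opts) {
    rows <- list()
    add <- function(name, rate, from, to, consumes = "", releases = "")
        rows[[length(rows) + 1L]] <<- data.frame(
            name = name, rate = rate, from = from, to = to,
            consumes = consumes, releases = releases,
            stringsAsFactors = FALSE)
    layers <- if (opts$orcLayer) c("", "P") else ""
    for (L in layers) {
        s <- function(i) paste0("S", i, L)
        add(paste0("Cdc6 binding", L), "kon6", s(0), s(1), "Cdc6")
        add(paste0("Cdc6 unbinding", L), "koff6", s(1), s(0), "", "Cdc6")
        if (L == "") {
            add("Cdt1.Mcm loading", "konL", s(1), s(2), "Cdt1Mcm")
            add("Cdt1.Mcm unbinding", "koffL", s(2), s(1), "", "Cdt1Mcm")
            add("Mcm loading (pre-RC)", "kload", s(2), s(3), "",
                "Cdc6+Cdt1")
        }
        add(paste0("Mcm phosphorylation", L), "kcatMcm", s(3), s(4))
        add(paste0("Cdc45 binding", L), "kon45", s(4), s(5), "Cdc45")
        add(paste0("Cdc45 unbinding", L), "koff45", s(5), s(4), "", "Cdc45")
        if (opts$bindingOrder == "solution") {
            add(paste0("11-3-2 binding", L), "konT", s(5), s(6), "Activator")
            add(paste0("11-3-2 unbinding", L), "koffT", s(6), s(5), "",
                "Activator")
            add(paste0("GINS.Pol binding", L), "konGPo", s(6), s(7),
                "GINSPol")
            add(paste0("GINS.Pol unbinding", L), "koffGPo", s(7), s(6), "",
                "GINSPol")
        } else {
            add(paste0("Dpb11.pSld3 docking", L), "konT", s(5), s(6),
                "Dpb11pSld3")
            add(paste0("Dpb11.pSld3 undocking", L), "koffT", s(6), s(5), "",
                "Dpb11pSld3")
            add(paste0("pSld2 + GINS.Pol recruitment", L), "konGPo",
                s(6), s(7), "pSld2+GINSPol")
        }
        add(paste0("activator release", L), "krel", s(7), s(8), "",
            "Activator")
        add(paste0("origin firing", L), "kfire", s(8), s(9))
    }
    if (opts$orcLayer)
        for (i in c(0, 1, 9))       # ORC exposed only at S0, S1 and S9
            add(paste0("ORC phosphorylation S", i), "kcatOrc",
                paste0("S", i), paste0("S", i, "P"))
    add("relicensing of fired origin", "k16", "S9", "S3", "Cdt1Mcm", "Cdt1")
    do.call(rbind, rows)
}

#' Number of origin states in a model
#' @param model ReplicationModel.
#' @export
stateCount <- function(model)
    if (model@options$orcLayer) 20L else 10L

#' Origin-state reaction list
#' @param model ReplicationModel.
#' @return data.frame with one origin-state conversion per row.
#' @export
reactionList <- function(model) model@reactions
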