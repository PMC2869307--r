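## Feasible ranges by reaction kind: standard diffusion-limited association,
## dissociation, enzymatic turnover and Michaelis-constant bounds, plus the
## dedicated range of the relicensing gate k16.
.kindBounds <- list(
    binding     = c(1e4, 1e9),    # 1/(M s)
    unbinding   = c(1e-4, 1e2),   # 1/s
    catalytic   = c(1e-3, 10),    # 1/s
    michaelis   = c(1e-8, 1e-4),  # M
    degradation = c(1e-5, 1),     # 1/s
    export      = c(1e-5, 1),     # 1/s
    relicensing = c(1e-6, 1e-2))  # 1/s

.kindUnits <- c(binding = "1/M/s", unbinding = "1/s", catalytic = "1/s",
                michaelis = "M", degradation = "1/s", export = "1/s",
                relicensing = "1/s")

.prow <- function(name, kind, value, module, optimizable,
                  pair = NA_character_, unit = NULL) {
    b <- .kindBounds[[kind]]
    data.frame(name = name, kind = kind, value = value,
               unit = if (is.null(unit)) unname(.kindUnits[kind]) else unit,
               module = module,
               low = b[1], high = b[2], optimizable = optimizable,
               pair = pair, stringsAsFactors = FALSE)
}

#' Default kinetic parameter set
#'
#' The licensing and S-Cdk-activation module constants are fixed such that
#' licensing of the early origins completes before S-Cdk becomes active and
#' S-Cdk rises with a delay of roughly 10--20 min after the G1-Cdk input.
#' The 11-3-2 activator and firing-module constants are the optimizable ones
#' and default to mid-range placeholder values; realistic kinetics are
#' obtained from [optimizeCoherence()] or the shipped [referenceParameters()].
#'
#' @return A [ParameterSet-class] object.
#' @export
defaultParameterSet <- function() {
    pr <- rbind(
        ## --- licensing module (fixed) ---
        .prow("kon6",   "binding",   2e6,  "licensing", FALSE, "koff6"),
        .prow("koff6",  "unbinding", 1e-3, "licensing", FALSE),
        .prow("konCM",  "binding",   1e6,  "licensing", FALSE, "koffCM"),
        .prow("koffCM", "unbinding", 1e-3, "licensing", FALSE),
        .prow("konL",   "binding",   2e6,  "licensing", FALSE, "koffL"),
        .prow("koffL",  "unbinding", 1e-3, "licensing", FALSE),
        .prow("kload",  "catalytic", 0.02, "licensing", FALSE),
        .prow("Kavail", "michaelis", 5e-8, "licensing", FALSE),
        .prow("kd6",    "degradation", 1e-3,  "licensing", FALSE),
        .prow("kexp",   "export",      5e-4,  "licensing", FALSE),
        ## --- S-Cdk activation module (fixed) ---
        .prow("kcatSic", "catalytic", 0.5,   "scdk", FALSE),
        .prow("KmSic",   "michaelis", 1e-6,  "scdk", FALSE),
        .prow("kpSic",   "catalytic", 3e4,   "scdk", FALSE, unit = "1/M/s"),
        .prow("kdegSic", "degradation", 8e-4,  "scdk", FALSE),
        .prow("konSC",   "binding",   1e7,   "scdk", FALSE, "koffSC"),
        .prow("koffSC",  "unbinding", 1e-4,  "scdk", FALSE),
        ## --- firing module (optimizable) ---
        .prow("kcatMcm", "catalytic", 0.5,  "firing", TRUE),
        .prow("KmMcm",   "michaelis", 1e-6, "firing", TRUE),
        .prow("kon45",   "binding",   1e6,  "firing", TRUE, "koff45"),
        .prow("koff45",  "unbinding", 1e-3, "firing", TRUE),
        .prow("konT",    "binding",   1e7,  "firing", TRUE, "koffT"),
        .prow("koffT",   "unbinding", 1e-3, "firing", TRUE),
        .prow("konGPo",  "binding",   1e6,  "firing", TRUE, "koffGPo"),
        .prow("koffGPo", "unbinding", 1e-3, "firing", TRUE),
        .prow("krel",    "catalytic", 0.05, "firing", TRUE),
        .prow("kfire",   "catalytic", 0.05, "firing", TRUE),
        .prow("kcatOrc", "catalytic", 0.1,  "firing", TRUE),
        .prow("KmOrc",   "michaelis", 1e-6, "firing", TRUE),
        .prow("k16",     "relicensing", 1e-3, "firing", TRUE),
        .prow("konGP0",  "binding",   1e6,  "firing", FALSE, "koffGP0"),
        .prow("koffGP0", "unbinding", 1e-3, "firing", FALSE),
        ## --- 11-3-2 activator module (optimizable) ---
        .prow("kcat2",   "catalytic", 1,    "activator", TRUE),
        .prow("Km2",     "michaelis", 1e-6, "activator", TRUE),
        .prow("kcatT84", "catalytic", 1,    "activator", TRUE),
        .prow("KmT84",   "michaelis", 1e-6, "activator", TRUE),
        .prow("kcat3",   "catalytic", 1,    "activator", TRUE),
        .prow("Km3",     "michaelis", 1e-6, "activator", TRUE),
        .prow("kcatP",   "catalytic", 0.5,  "activator", TRUE),
        .prow("KmP",     "michaelis", 3e-6, "activator", TRUE),
        .prow("konD2",   "binding",   1e7,  "activator", TRUE, "koffD2"),
        .prow("koffD2",  "unbinding", 1e-2, "activator", TRUE),
        .prow("konD3",   "binding",   1e7,  "activator", TRUE, "koffD3"),
        .prow("koffD3",  "unbinding", 1e-2, "activator", TRUE),
        .prow("konT2",   "binding",   1e7,  "activator", TRUE, "koffT2"),
        .prow("koffT2",  "unbinding", 1e-2, "activator", TRUE),
        .prow("konT3",   "binding",   1e7,  "activator", TRUE, "koffT3"),
        .prow("koffT3",  "unbinding", 1e-2, "activator", TRUE))
    new("ParameterSet", params = pr)
}

#' Get a rate-constant value
#' @param ps ParameterSet.
#' @param name parameter name(s).
#' @return numeric vector of values.
#' @export
paramValue <- function(ps, name) {
    stopifnot(is(ps, "ParameterSet"))
    i <- match(name, ps@params$name)
    if (anyNA(i)) stop("unknown parameter: ",
                       paste(name[is.na(i)], collapse = ", "))
    setNames(ps@params$value[i], name)
}

#' Replace rate-constant values
#' @param ps ParameterSet.
#' @param values named numeric vector of new values.
#' @param check validate the result (default TRUE).
#' @return modified ParameterSet.
#' @export
setParamValues <- function(ps, values, check = TRUE) {
    stopifnot(is(ps, "ParameterSet"))
    i <- match(names(values), ps@params$name)
    if (anyNA(i)) stop("unknown parameter: ",
                       paste(names(values)[is.na(i)], collapse = ", "))
    ps@params$value[i] <- unname(values)
    if (check) validObject(ps)
    ps
}

#' Names of the optimizable parameters (activator + firing modules)
#' @param ps ParameterSet.
#' @return character vector.
#' @export
optimizableParams <- function(ps) ps@params$name[ps@params$optimizable]

#' Parameter table as a data.frame
#' @param ps ParameterSet.
#' @return the underlying data.frame.
#' @export
paramTable <- function(ps) ps@params

#' Dissociation constants of all binding reactions
#'
#' @param ps ParameterSet.
#' @return data.frame with reaction (on-rate name), Kd in molar.
#' @export
bindingAffinities <- function(ps) {
    pr <- ps@params
    onr <- pr[pr$kind == "binding", ]
    koff <- pr$value[match(onr$pair, pr$name)]
    data.frame(reaction = onr$name, kon = onr$value, koff = koff,
               Kd = koff / onr$value, stringsAsFactors = FALSE)
}
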