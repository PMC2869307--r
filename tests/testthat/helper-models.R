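## Shared fixtures built in code.

## a model with every kinase, licensing and firing rate silenced: nothing
## can leave S0
frozenModel <- function() {
    ps <- defaultParameterSet()
    silence <- setdiff(ps@params$name[ps@params$kind != "michaelis"],
                       c("koff6", "koffCM", "koffL", "koffSC"))
    ps@params$value[ps@params$name %in% silence] <- 1e-300
    ps@params$value[ps@params$name == "k16"] <- 0
    ps@params$optimizable <- FALSE
    buildModel(params = ps)
}

## licensing-only linear chain S0 -> S1 -> S2 -> S3 with clamped pools and
## unbinding switched off; returns model plus the three effective rates
licensingChainModel <- function() {
    ps <- defaultParameterSet()
    off <- c("koff6", "koffCM", "koffL", "koffSC")
    zero <- c("kcatMcm", "kcatOrc", "kcat2", "kcatT84", "kcat3", "kcatSic",
              "kcatP", "kpSic", "kdegSic", "kd6", "kexp", "k16",
              "kon45", "konT", "konGPo", "konD2", "konD3", "konT2", "konT3",
              "krel", "kfire", "konCM", "konGP0", "konSC")
    ps@params$value[ps@params$name %in% c(off, zero)] <- 1e-300
    ps@params$value[ps@params$name == "k16"] <- 0
    ps@params$optimizable <- FALSE
    m <- buildModel(params = ps, clampPools = TRUE)
    r1 <- paramValue(ps, "kon6") * m@y0[["Cdc6"]]
    ## Cdt1.Mcm starts empty under clamping; preload it explicitly
    m@y0[["Cdt1Mcm"]] <- m@y0[["Cdt1"]]
    r2 <- paramValue(ps, "konL") * m@y0[["Cdt1Mcm"]]
    r3 <- paramValue(ps, "kload")
    list(model = m, rates = unname(c(r1, r2, r3)))
}

## small admissible-like parameter set: the shipped reference fixture
refParams <- function() referenceParameters()$params

trapzNum <- function(x, y)
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
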