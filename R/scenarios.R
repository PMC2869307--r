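#' Scenario specification
#'
#' A named bundle of overrides applied on top of a base parameter set and
#' protein pool: abundance changes, rate-constant changes and structural
#' option changes (phosphosite counts, constitutive-activity flags).
#' Overrides must reference existing quantities; bases are never modified.
#'
#' @param name scenario name.
#' @param poolOverrides named numeric vector of molecule counts.
#' @param paramOverrides named numeric vector of rate constants.
#' @param optionOverrides named list of [buildModel()] options.
#' @return list of class "ScenarioSpec".
#' @export
scenarioSpec <- function(name, poolOverrides = numeric(0),
                         paramOverrides = numeric(0),
                         optionOverrides = list()) {
    structure(list(name = name, poolOverrides = poolOverrides,
                   paramOverrides = paramOverrides,
                   optionOverrides = optionOverrides),
              class = "ScenarioSpec")
}

#' Wildtype scenario (no overrides)
#' @export
wildtypeScenario <- function() scenarioSpec("wildtype")

#' Slow Sic1 degradation (suboptimal growth conditions)
#'
#' Sic1 degradation slowed by `factor` (default 5), delaying S-Cdk
#' accumulation and origin firing.
#'
#' @param params base ParameterSet (for the wildtype degradation rate).
#' @param factor slow-down factor.
#' @export
slowSic1Scenario <- function(params = defaultParameterSet(), factor = 5)
    scenarioSpec("slow_sic1",
                 paramOverrides = c(kdegSic =
                     unname(paramValue(params, "kdegSic")) / factor))

#' Sic1 deletion scenario
#'
#' No Sic1, so S-Cdk is active from t = 0 but -- as reported for the mutant
#' -- at a reduced amplitude (50% of wildtype S-Cdk by default).
#'
#' @param pools base ProteinPool.
#' @param scdkFactor S-Cdk amplitude relative to wildtype (default 0.5).
#' @export
deltaSic1Scenario <- function(pools = defaultProteinPool(),
                              scdkFactor = 0.5)
    scenarioSpec("delta_sic1",
                 poolOverrides = c(Sic1 = 0,
                     SCdk = unname(poolCount(pools, "SCdk")) * scdkFactor))

#' Constitutively active Sld2/Sld3 with non-degradable Sic1 (sic1-delta-NT)
#'
#' Sld2 and Sld3 are fully active from t = 0 (phospho-chains bypassed) and
#' Sic1 degradation is disabled, leaving S-Cdk strongly reduced.
#'
#' @export
constitutiveSldSpec <- function()
    scenarioSpec("constitutive_sld",
                 paramOverrides = c(kdegSic = 0),
                 optionOverrides = list(constitutiveSld2 = TRUE,
                                        constitutiveSld3 = TRUE))

#' Run a scenario
#'
#' Applies the overrides, runs the paired simulations (k16 on/off), computes
#' firing metrics, the unlicensed-origin fraction, and a replicon summary
#' obtained by placing origins from the spacing sampler and drawing firing
#' times from the simulated density.
#'
#' @param spec ScenarioSpec.
#' @param params,pools base ParameterSet and ProteinPool (left unmodified).
#' @param horizon,dt,rtol,atol solver settings.
#' @param replicons compute the replicon summary (default TRUE).
#' @param seed RNG seed for origin placement and firing-time draws.
#' @param forkSpeed fork speed in kb/min.
#' @param ... additional fixed structural options for [buildModel()].
#' @return list with name, metrics, unlicensedFraction, replicon summary,
#'   and the two trajectories.
#' @export
runScenario <- function(spec, params = defaultParameterSet(),
                        pools = defaultProteinPool(), horizon = 10800,
                        dt = 20, rtol = 1e-8, atol = 1e-12,
                        replicons = TRUE, seed = 1, forkSpeed = 1.5, ...) {
    stopifnot(inherits(spec, "ScenarioSpec"))
    if (length(spec$poolOverrides))
        pools <- setPoolCounts(pools, spec$poolOverrides)
    if (length(spec$paramOverrides))
        params <- setParamValues(params, spec$paramOverrides, check = FALSE)
    opts <- c(spec$optionOverrides, list(...))
    known <- c("orcLayer", "nSic1", "nSld2", "nSld3", "constitutiveSld2",
               "constitutiveSld3", "bindingOrder", "clampPools", "M")
    if (length(bad <- setdiff(names(opts), known)))
        stop("unknown option override: ", paste(bad, collapse = ", "))
    build <- function(ps) do.call(buildModel,
        c(list(pools = pools, params = ps), opts))
    m1 <- build(params)
    m0 <- build(setParamValues(params, c(k16 = 0), check = FALSE))
    t1 <- simulateModel(m1, horizon = horizon, dt = dt, rtol = rtol,
                        atol = atol)
    t0 <- simulateModel(m0, horizon = horizon, dt = dt, rtol = rtol,
                        atol = atol)
    metrics <- firingMetrics(t1, t0)
    ## origins that never complete licensing sit in S0..S2 / S0P..S2P at the
    ## horizon (pre-RC formation blocked or pools depleted)
    lastRow <- originStates(t1)[length(t1@time), ]
    unlicensed <- sum(lastRow[c("S0", "S1", "S2", "S0P", "S1P", "S2P")])
    repl <- NULL
    if (replicons && is.finite(metrics$N) && metrics$N > 1) {
        M <- m1@options$M
        pos <- placeOrigins(spacingSampler(), n = M, seed = seed)
        tim <- assignFiringTimes(firingProfile(t1), n = M,
                                 seed = seed + 1, units = "min")
        map <- computeReplicons(pos, tim, v = forkSpeed)
        repl <- repliconSummary(map)
        repl$map <- map
    }
    list(name = spec$name, metrics = metrics,
         unlicensedFraction = unname(unlicensed),
         replicons = repl, trajectory = t1, trajectory0 = t0)
}

#' Constitutive-Sld2/3 scenario runner
#'
#' Convenience wrapper running [constitutiveSldSpec()] and reporting the
#' rereplicating fraction rho/N0, the firing duration including refiring,
#' and the passive-replication fraction.
#'
#' @param params,pools base objects.
#' @param ... forwarded to [runScenario()].
#' @return the [runScenario()] result with an added `summaryStats` list.
#' @export
constitutiveSldScenario <- function(params = defaultParameterSet(),
                                    pools = defaultProteinPool(), ...) {
    r <- runScenario(constitutiveSldSpec(), params = params, pools = pools,
                     ...)
    r$summaryStats <- list(
        rereplicatingFraction = r$metrics$rho / max(r$metrics$N0, 1e-9),
        Delta_min = r$metrics$Delta_min,
        passiveFraction = if (!is.null(r$replicons))
            r$replicons$passiveFraction else NA_real_)
    r
}

#' S-Cdk titration
#'
#' Varies the number of S-Cdk molecules (Sic1 regulation unchanged) and
#' reports all four firing statistics per grid point.
#'
#' @param grid vector of S-Cdk molecule counts.
#' @param params,pools base objects.
#' @param ... forwarded to [runScenario()] (replicons disabled).
#' @return data.frame with SCdk, N, N0, rho, tau_min, Delta_min.
#' @export
scdkTitration <- function(grid, params = defaultParameterSet(),
                          pools = defaultProteinPool(), ...) {
    rows <- lapply(grid, function(count) {
        sp <- scenarioSpec(paste0("scdk_", count),
                           poolOverrides = c(SCdk = count))
        r <- runScenario(sp, params = params, pools = pools,
                         replicons = FALSE, ...)
        data.frame(SCdk = count, N = r$metrics$N, N0 = r$metrics$N0,
                   rho = r$metrics$rho, tau_min = r$metrics$tau_min,
                   Delta_min = r$metrics$Delta_min)
    })
    do.call(rbind, rows)
}

#' Phosphosite-number variation
#'
#' Runs the network for each requested combination of phosphosite counts in
#' Sic1, Sld2 (random sites preceding Thr84; the total number of activating
#' steps is nSld2 + 1) and Sld3.
#'
#' @param combos data.frame with columns nSic1, nSld2, nSld3.
#' @param params,pools base objects.
#' @param ... forwarded to [runScenario()].
#' @return data.frame with the combination, firing metrics and S-phase
#'   length.
#' @export
phosphositeVariation <- function(combos, params = defaultParameterSet(),
                                 pools = defaultProteinPool(), ...) {
    stopifnot(all(c("nSic1", "nSld2", "nSld3") %in% names(combos)))
    rows <- lapply(seq_len(nrow(combos)), function(i) {
        sp <- scenarioSpec(sprintf("sites_%d_%d_%d", combos$nSic1[i],
                                   combos$nSld2[i], combos$nSld3[i]),
                           optionOverrides = list(nSic1 = combos$nSic1[i],
                                                  nSld2 = combos$nSld2[i],
                                                  nSld3 = combos$nSld3[i]))
        r <- runScenario(sp, params = params, pools = pools, ...)
        data.frame(nSic1 = combos$nSic1[i], nSld2 = combos$nSld2[i],
                   nSld3 = combos$nSld3[i], N = r$metrics$N,
                   N0 = r$metrics$N0, rho = r$metrics$rho,
                   tau_min = r$metrics$tau_min,
                   Delta_min = r$metrics$Delta_min,
                   sPhaseMin = if (!is.null(r$replicons))
                       r$replicons$sPhaseMin else NA_real_)
    })
    do.call(rbind, rows)
}
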