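#' Draw a random kinetic parameter set
#'
#' Log-uniform sampling of every optimizable rate constant (11-3-2 activator
#' and firing modules) within its biochemically feasible bounds; the
#' licensing and S-Cdk-activation module constants stay fixed.
#'
#' @param params base ParameterSet (defines bounds and fixed values).
#' @param seed optional RNG seed.
#' @return a new ParameterSet with resampled optimizable entries.
#' @export
sampleRandomParameters <- function(params = defaultParameterSet(),
                                   seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    pr <- params@params
    i <- which(pr$optimizable)
    lo <- log10(pr$low[i]); hi <- log10(pr$high[i])
    pr$value[i] <- 10^(lo + runif(length(i)) * (hi - lo))
    new("ParameterSet", params = pr)
}

#' Evaluate one candidate parameter set
#'
#' Runs the paired simulations (k16 as given and k16 = 0), computes the
#' firing statistics and flags feasibility N >= Nmin and rho <= rhoMax.
#' Integration failures mark the candidate infeasible instead of raising.
#'
#' @param params ParameterSet.
#' @param pools ProteinPool.
#' @param Nmin,rhoMax feasibility constraints (defaults 180 and 0.01).
#' @param horizon,dt,rtol,atol solver settings.
#' @param ... structural options for [buildModel()].
#' @return list(N, N0, rho, tau_min, Delta_min, feasible, ok, message).
#' @export
evaluateCandidate <- function(params, pools = defaultProteinPool(),
                              Nmin = 180, rhoMax = 0.01,
                              horizon = 10800, dt = 30,
                              rtol = 1e-8, atol = 1e-12, maxsteps = 20000,
                              ...) {
    res <- try({
        m1 <- buildModel(pools = pools, params = params, ...)
        m0 <- buildModel(pools = pools,
                         params = setParamValues(params, c(k16 = 0)), ...)
        t1 <- simulateModel(m1, horizon = horizon, dt = dt, rtol = rtol,
                            atol = atol, maxsteps = maxsteps)
        t0 <- simulateModel(m0, horizon = horizon, dt = dt, rtol = rtol,
                            atol = atol, maxsteps = maxsteps)
        firingMetrics(t1, t0)
    }, silent = TRUE)
    if (inherits(res, "try-error"))
        return(list(N = NA_real_, N0 = NA_real_, rho = NA_real_,
                    tau_min = NA_real_, Delta_min = NA_real_,
                    feasible = FALSE, ok = FALSE,
                    message = attr(res, "condition")$message))
    res$feasible <- is.finite(res$N) && res$N >= Nmin && res$rho <= rhoMax
    res$ok <- TRUE
    res$message <- ""
    res
}

#' Random-parameter screening
#'
#' Samples n parameter sets, evaluates each over a long horizon and reports
#' the firing statistics together with the "functional" classification
#' (fraction of fired origins > minFraction and rho < rhoMax).
#'
#' @param n number of random draws.
#' @param params base ParameterSet.
#' @param pools ProteinPool.
#' @param seed RNG seed for the whole screen.
#' @param horizon screening horizon in seconds (default 12 h).
#' @param minFraction functional threshold on N/M (default 0.95).
#' @param rhoMax functional threshold on rho (default 0.01).
#' @param dt,rtol output/solver settings (screening uses a relaxed rtol).
#' @param M origin number.
#' @param verbose print progress every 50 draws.
#' @return data.frame with one row per draw: N, N0, rho, tau_min, Delta_min,
#'   ok, functional.
#' @export
screenParameters <- function(n, params = defaultParameterSet(),
                             pools = defaultProteinPool(), seed = 1,
                             horizon = 43200, minFraction = 0.95,
                             rhoMax = 0.01, dt = 60, rtol = 1e-6, M = 190,
                             verbose = FALSE) {
    set.seed(seed)
    seeds <- sample.int(2^30, n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        ps <- sampleRandomParameters(params, seed = seeds[i])
        ev <- evaluateCandidate(ps, pools, Nmin = minFraction * M,
                                rhoMax = rhoMax, horizon = horizon, dt = dt,
                                rtol = rtol, M = M)
        rows[[i]] <- data.frame(draw = i, N = ev$N, N0 = ev$N0, rho = ev$rho,
                                tau_min = ev$tau_min,
                                Delta_min = ev$Delta_min, ok = ev$ok)
        if (verbose && i %% 50 == 0) message("screened ", i, "/", n)
    }
    out <- do.call(rbind, rows)
    out$functional <- out$ok & !is.na(out$N) &
        out$N / M > minFraction & !is.na(out$rho) & out$rho < rhoMax
    out
}

#' Optimizer configuration
#'
#' @param Nmin required number of firing origins (default 180 of 190).
#' @param rhoMax permitted rereplication (default 0.01 origins).
#' @param popSize DE population size (default 24).
#' @param generations maximal DE generations (default 60).
#' @param stagnation early stop after this many stagnant generations.
#' @param F,CR DE differential weight and crossover rate.
#' @param w1,w2 penalty weights for the N and rho constraints.
#' @param horizon,dt,rtol solver settings for objective evaluations.
#' @return list of class "OptimizationConfig".
#' @export
optimizationConfig <- function(Nmin = 180, rhoMax = 0.01, popSize = 16,
                               generations = 12, stagnation = 6,
                               F = 0.7, CR = 0.9, w1 = 10, w2 = 1e5,
                               horizon = 7200, dt = 60, rtol = 1e-6,
                               maxsteps = 5000) {
    stopifnot(Nmin > 0, rhoMax >= 0, popSize >= 5)
    structure(list(Nmin = Nmin, rhoMax = rhoMax, popSize = popSize,
                   generations = generations, stagnation = stagnation,
                   F = F, CR = CR, w1 = w1, w2 = w2, horizon = horizon,
                   dt = dt, rtol = rtol, maxsteps = maxsteps),
              class = "OptimizationConfig")
}

## penalized objective: firing duration in minutes plus quadratic/linear
## constraint penalties scaled to dominate Delta
.penalizedObjective <- function(ev, cfg) {
    if (!ev$ok || !is.finite(ev$N)) return(1e8)
    d <- if (is.finite(ev$Delta_min)) ev$Delta_min else 1e4
    pen <- cfg$w1 * max(0, cfg$Nmin - ev$N)^2 +
        cfg$w2 * max(0, ev$rho - cfg$rhoMax)
    d + pen
}

#' Constrained minimization of the firing duration
#'
#' Differential evolution (rand/1/bin with elitism) over the log10-scaled
#' optimizable parameters, minimizing the firing duration Delta subject to
#' the constraints N >= Nmin and rho <= rhoMax handled by penalty.
#'
#' @param config OptimizationConfig.
#' @param params base ParameterSet (bounds + fixed modules).
#' @param pools ProteinPool.
#' @param seed RNG seed of the run.
#' @param init optional ParameterSet included in the initial population.
#' @param verbose print per-generation best objective.
#' @param ... structural options for [buildModel()].
#' @return list(params = best ParameterSet, metrics, feasible, objective,
#'   trace, seed).
#' @export
optimizeCoherence <- function(config = optimizationConfig(),
                              params = defaultParameterSet(),
                              pools = defaultProteinPool(),
                              seed = 1, init = NULL, verbose = FALSE, ...) {
    set.seed(seed)
    pr <- params@params
    ## k16 stays fixed under optimization: the relicensing propensity is a
    ## property of the origin biochemistry, not a tunable of the cell
    oi <- which(pr$optimizable & pr$name != "k16")
    d <- length(oi)
    lo <- log10(pr$low[oi]); hi <- log10(pr$high[oi])
    toPS <- function(x) setParamValues(params,
        setNames(10^x, pr$name[oi]), check = FALSE)
    evalx <- function(x) {
        ev <- evaluateCandidate(toPS(x), pools, Nmin = config$Nmin,
                                rhoMax = config$rhoMax,
                                horizon = config$horizon, dt = config$dt,
                                rtol = config$rtol,
                                maxsteps = config$maxsteps, ...)
        list(obj = .penalizedObjective(ev, config), ev = ev)
    }
    np <- config$popSize
    pop <- matrix(runif(np * d, lo, hi), nrow = np, byrow = TRUE)
    if (!is.null(init)) pop[1, ] <- log10(paramValue(init, pr$name[oi]))
    evals <- apply(pop, 1, evalx)
    objs <- vapply(evals, `[[`, 0, "obj")
    trace <- numeric(0)
    stag <- 0
    for (g in seq_len(config$generations)) {
        bestPrev <- min(objs)
        for (i in seq_len(np)) {
            r <- sample(setdiff(seq_len(np), i), 3)
            mut <- pop[r[1], ] + config$F * (pop[r[2], ] - pop[r[3], ])
            mut <- pmin(pmax(mut, lo), hi)
            cross <- runif(d) < config$CR
            cross[sample.int(d, 1)] <- TRUE
            cand <- ifelse(cross, mut, pop[i, ])
            ce <- evalx(cand)
            if (ce$obj <= objs[i]) {       # elitist selection
                pop[i, ] <- cand
                objs[i] <- ce$obj
                evals[[i]] <- ce
            }
        }
        trace <- c(trace, min(objs))
        stag <- if (min(objs) < bestPrev - 1e-6) 0 else stag + 1
        if (verbose) message("gen ", g, " best ", signif(min(objs), 5))
        if (stag >= config$stagnation) break
    }
    b <- which.min(objs)
    ## re-evaluate the winner at the standard horizon and tolerance
    bestPS <- toPS(pop[b, ])
    fin <- evaluateCandidate(bestPS, pools, Nmin = config$Nmin,
                             rhoMax = config$rhoMax, horizon = 10800,
                             dt = 30, rtol = 1e-7, ...)
    list(params = bestPS, metrics = fin,
         feasible = isTRUE(fin$feasible), objective = objs[b],
         trace = trace, seed = seed)
}

#' Collect an ensemble of admissible optimized parameter sets
#'
#' Runs the constrained optimizer from several random initializations and
#' keeps the feasible results, mirroring the strategy of admitting several
#' local optima rather than searching for the global one.
#'
#' @param nRuns number of optimizer runs.
#' @param config OptimizationConfig.
#' @param params,pools base parameter set and protein pool.
#' @param seeds vector of per-run seeds (default 1:nRuns).
#' @param verbose forwarded to [optimizeCoherence()].
#' @param ... structural options for [buildModel()].
#' @return An [AdmissibleEnsemble-class] object (possibly empty).
#' @export
collectEnsemble <- function(nRuns, config = optimizationConfig(),
                            params = defaultParameterSet(),
                            pools = defaultProteinPool(),
                            seeds = seq_len(nRuns), verbose = FALSE, ...) {
    stopifnot(nRuns >= 1, length(seeds) == nRuns)
    members <- list(); rows <- list()
    for (k in seq_len(nRuns)) {
        r <- optimizeCoherence(config, params, pools, seed = seeds[k],
                               verbose = verbose, ...)
        if (r$feasible) {
            members[[length(members) + 1L]] <- r$params
            rows[[length(rows) + 1L]] <-
                data.frame(seed = seeds[k], N = r$metrics$N,
                           N0 = r$metrics$N0, rho = r$metrics$rho,
                           tau_min = r$metrics$tau_min,
                           Delta_min = r$metrics$Delta_min)
        }
    }
    metrics <- if (length(rows)) do.call(rbind, rows) else
        data.frame(seed = numeric(0), N = numeric(0), N0 = numeric(0),
                   rho = numeric(0), tau_min = numeric(0),
                   Delta_min = numeric(0))
    new("AdmissibleEnsemble", members = members, metrics = metrics,
        provenance = list(seeds = seeds, config = config))
}

#' Ensemble members
#' @param ensemble AdmissibleEnsemble.
#' @export
ensembleMembers <- function(ensemble) ensemble@members

#' Ensemble metrics table
#' @param ensemble AdmissibleEnsemble.
#' @export
ensembleMetrics <- function(ensemble) ensemble@metrics

#' Mean binding affinities across an ensemble
#'
#' Dissociation constants Kd = k_off/k_on per binding reaction (and the
#' Michaelis constants of the regulatory phosphorylations), averaged over
#' the ensemble members both arithmetically and geometrically.
#'
#' @param ensemble AdmissibleEnsemble.
#' @return data.frame with reaction, meanKd, geomMeanKd (molar).
#' @export
ensembleAffinities <- function(ensemble) {
    stopifnot(length(ensemble@members) > 0)
    tabs <- lapply(ensemble@members, function(ps) {
        ba <- bindingAffinities(ps)
        km <- ps@params[ps@params$kind == "michaelis" &
                        ps@params$optimizable, c("name", "value")]
        rbind(data.frame(reaction = ba$reaction, Kd = ba$Kd),
              data.frame(reaction = km$name, Kd = km$value))
    })
    kd <- sapply(tabs, `[[`, "Kd")
    if (is.null(dim(kd))) kd <- matrix(kd, ncol = length(tabs))
    data.frame(reaction = tabs[[1]]$reaction,
               meanKd = rowMeans(kd),
               geomMeanKd = exp(rowMeans(log(kd))),
               stringsAsFactors = FALSE)
}
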