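test_that("random draws are log-uniform within the feasible bounds and only
           touch the optimizable modules", {
    base <- defaultParameterSet()
    ps <- sampleRandomParameters(base, seed = 1)
    pr <- paramTable(ps); b <- paramTable(base)
    i <- pr$optimizable
    expect_true(all(pr$value[i] >= pr$low[i] & pr$value[i] <= pr$high[i]))
    expect_equal(pr$value[!i], b$value[!i])   # fixed modules untouched
    ## log-uniformity of one parameter over many draws (KS test)
    set.seed(3)
    draws <- replicate(2000, paramValue(sampleRandomParameters(base),
                                        "konT"))
    lo <- log10(b$low[b$name == "konT"]); hi <- log10(b$high[b$name == "konT"])
    ks <- stats::ks.test((log10(draws) - lo) / (hi - lo), "punif")
    expect_lt(unname(ks$statistic), 0.04)
})

test_that("candidate evaluation flags infeasibility and closed-gate
           consistency", {
    ## all firing silenced: no origin can fire
    ps <- defaultParameterSet()
    ps@params$value[ps@params$name == "kfire"] <- 1e-300
    ps@params$optimizable <- FALSE
    ev <- evaluateCandidate(ps, horizon = 1800, dt = 60, rtol = 1e-6)
    expect_true(ev$ok)
    expect_lt(ev$N, 1e-3)
    expect_false(ev$feasible)
    ## k16 = 0 candidate: rho identically 0, feasibility reduces to N
    ps2 <- setParamValues(refParams(), c(k16 = 0))
    ev2 <- evaluateCandidate(ps2, rtol = 1e-6, dt = 60)
    expect_equal(ev2$rho, 0, tolerance = 1e-6)
    expect_equal(ev2$feasible, ev2$N >= 180)
})

test_that("differential evolution matches an exhaustive log-grid search on
           a 3-parameter subproblem", {
    ## free parameters: Cdc45 on-rate, activator on-rate, firing rate; all
    ## other optimizables pinned to the reference fixture
    base <- refParams()
    free <- c("kon45", "konT", "kfire")
    pr <- base@params
    pr$optimizable <- pr$name %in% free
    base3 <- new("ParameterSet", params = pr)
    cfg <- optimizationConfig(popSize = 10, generations = 8, stagnation = 8,
                              horizon = 7200, dt = 60, rtol = 1e-5)
    evalObj <- function(v) {
        ps <- setParamValues(base3, setNames(v, free), check = FALSE)
        ev <- evaluateCandidate(ps, horizon = 7200, dt = 60, rtol = 1e-5,
                                maxsteps = 5000)
        RepliNet:::.penalizedObjective(ev, cfg)
    }
    ## coarse 5^3 log-grid oracle
    grid <- lapply(free, function(nm) {
        i <- match(nm, pr$name)
        10^seq(log10(pr$low[i]), log10(pr$high[i]), length.out = 5)
    })
    combos <- expand.grid(grid[[1]], grid[[2]], grid[[3]])
    gobj <- apply(combos, 1, evalObj)
    r <- optimizeCoherence(cfg, base3, seed = 5)
    expect_true(r$feasible)
    ## DE must do at least as well as the best grid point (same objective)
    expect_lte(r$objective, min(gobj) * 1.05 + 0.05)
})

test_that("optimizer contract: never worse than a feasible start, and the
           penalized best is monotone over generations", {
    cfg <- optimizationConfig(popSize = 8, generations = 4, stagnation = 4)
    start <- refParams()
    ev0 <- evaluateCandidate(start, horizon = cfg$horizon, dt = cfg$dt,
                             rtol = cfg$rtol, maxsteps = cfg$maxsteps)
    r <- optimizeCoherence(cfg, seed = 2, init = start)
    expect_true(all(diff(r$trace) <= 1e-9))
    expect_lte(r$objective,
               RepliNet:::.penalizedObjective(ev0, cfg) + 1e-3)
})

test_that("ensemble affinities are Kd ratios with consistent means", {
    ens <- new("AdmissibleEnsemble",
               members = list(refParams()),
               metrics = data.frame(seed = 1, N = 190, N0 = 190, rho = 0,
                                    tau_min = 40, Delta_min = 2),
               provenance = list())
    aff <- ensembleAffinities(ens)
    ba <- bindingAffinities(refParams())
    i <- match(ba$reaction, aff$reaction)
    expect_equal(aff$meanKd[i], ba$Kd)
    expect_equal(aff$geomMeanKd[i], ba$Kd)   # single member: means agree
})
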