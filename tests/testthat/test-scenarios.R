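test_that("wildtype scenario reproduces the base simulation and leaves the
           base objects untouched", {
    ps <- refParams()
    pool <- defaultProteinPool()
    psBefore <- paramTable(ps); poolBefore <- pool@counts
    r <- runScenario(wildtypeScenario(), params = ps, pools = pool,
                     replicons = FALSE)
    ev <- evaluateCandidate(ps, pool)
    expect_equal(r$metrics$N, ev$N, tolerance = 1e-5)
    expect_equal(r$metrics$tau_min, ev$tau_min, tolerance = 1e-4)
    expect_identical(paramTable(ps), psBefore)
    expect_identical(pool@counts, poolBefore)
})

test_that("unknown override targets raise configuration errors", {
    expect_error(runScenario(scenarioSpec("x",
        poolOverrides = c(NoProtein = 1)), params = refParams()),
        "unknown protein")
    expect_error(runScenario(scenarioSpec("x",
        paramOverrides = c(noRate = 1)), params = refParams()),
        "unknown parameter")
    expect_error(runScenario(scenarioSpec("x",
        optionOverrides = list(bogus = 1)), params = refParams()),
        "unknown option")
})

test_that("slow Sic1 degradation delays and desynchronizes firing without
           rereplication", {
    ps <- refParams()
    wt <- runScenario(wildtypeScenario(), params = ps, replicons = FALSE)
    sl <- runScenario(slowSic1Scenario(ps), params = ps, replicons = FALSE)
    expect_gt(sl$metrics$tau_min, wt$metrics$tau_min)
    expect_gt(sl$metrics$Delta_min, wt$metrics$Delta_min)
    expect_lt(sl$metrics$rho, 0.01)
})

test_that("sic1 deletion blocks licensing at a sizable fraction of origins
           while firing the rest early", {
    ps <- refParams()
    wt <- runScenario(wildtypeScenario(), params = ps, replicons = FALSE)
    ds <- runScenario(deltaSic1Scenario(), params = ps, replicons = FALSE)
    expect_gt(ds$unlicensedFraction, 0.1)
    expect_lt(ds$metrics$N, wt$metrics$N)
    ## the licensed remainder fires earlier than in wildtype
    if (is.finite(ds$metrics$tau_min))
        expect_lt(ds$metrics$tau_min, wt$metrics$tau_min)
})

test_that("constitutive Sld2/3 with stable Sic1 fires prematurely and
           rereplicates massively", {
    cs <- constitutiveSldScenario(params = refParams(), seed = 2)
    wt <- runScenario(wildtypeScenario(), params = refParams(),
                      replicons = FALSE)
    expect_lt(cs$metrics$tau_min, wt$metrics$tau_min)   # fires earlier
    expect_gt(cs$metrics$rho, 1)                        # massive vs < 0.01
    expect_gt(cs$metrics$rho / cs$metrics$N0, 0.02)
})

test_that("the S-Cdk titration has an essential-activator limit and an
           optimal window", {
    ps <- refParams()
    tt <- scdkTitration(c(0, 400, 1500), params = ps, rtol = 1e-6, dt = 60)
    expect_equal(tt$N[1], 0, tolerance = 1e-6)  # no S-Cdk, no firing
    expect_gt(tt$N[2], 180)                     # inside the robust window
    expect_lt(tt$rho[2], 0.01)
    expect_lt(tt$N[3], 100)                     # licensing inhibited
})

test_that("phosphosite variation: single-site Sic1 leaves firing nearly
           unchanged; fewer Sld2 steps advance firing and increase
           rereplication", {
    ps <- refParams()
    pv <- phosphositeVariation(data.frame(nSic1 = c(6, 1), nSld2 = 6,
                                          nSld3 = 2),
                               params = ps, replicons = FALSE,
                               rtol = 1e-6, dt = 30)
    base <- pv[1, ]; sic1 <- pv[2, ]
    expect_lt(abs(sic1$rho - base$rho), 0.01)
    ## firing-time shift buffered by the downstream Sld2 chain
    expect_lt(abs(sic1$tau_min - base$tau_min) / base$tau_min, 0.25)
    ## Sld2-step reduction probed on the default parameter set, where the
    ## activator chain carries the pre-firing delay
    pv2 <- phosphositeVariation(data.frame(nSic1 = 6, nSld2 = c(6, 3, 0),
                                           nSld3 = 2),
                                params = defaultParameterSet(),
                                replicons = FALSE, rtol = 1e-6, dt = 30)
    expect_true(all(diff(pv2$tau_min) < 0))   # premature firing
    expect_true(all(diff(pv2$rho) > 0))       # monotone rereplication rise
})
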