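test_that("parameter set respects bounds, positivity and Kd pairing", {
    ps <- defaultParameterSet()
    expect_true(validObject(ps))
    pr <- paramTable(ps)
    expect_true(all(pr$value[pr$name != "k16"] > 0))
    opt <- pr[pr$optimizable, ]
    expect_true(all(opt$value >= opt$low & opt$value <= opt$high))
    expect_true(all(opt$module %in% c("firing", "activator")))
    ba <- bindingAffinities(ps)
    expect_true(all(is.finite(ba$Kd) & ba$Kd > 0))
    ## Kd is invariant under joint scaling of kon and koff
    ps2 <- setParamValues(ps,
        c(kon45 = 10 * unname(paramValue(ps, "kon45")),
          koff45 = 10 * unname(paramValue(ps, "koff45"))), check = FALSE)
    expect_equal(bindingAffinities(ps2)["kon45" ==
                     bindingAffinities(ps2)$reaction, "Kd"],
                 ba[ba$reaction == "kon45", "Kd"])
})

test_that("pool conversions round-trip and are monotone", {
    pool <- defaultProteinPool()
    expect_equal(unname(poolCount(pool, "Sld3")), 130)
    cnt <- poolCount(pool, names(pool@counts))
    expect_equal(unname(molarToCount(countToMolar(cnt))), unname(cnt))
    ## one molecule in 2e-15 L is about 0.83 nM
    expect_equal(countToMolar(1) * 1e9, 0.83, tolerance = 0.01)
    ## stable replisome factors in the thousands, transient in the hundreds
    expect_true(all(poolCount(pool, c("Mcm", "Cdc45", "GINS")) >= 1000))
    expect_true(all(poolCount(pool, c("Sld2", "Sld3", "Dpb11", "SCdk")) <=
                    1000))
    expect_error(defaultProteinPool(c(NoSuch = 5)), "unknown protein")
})

test_that("G1-Cdk input is a nondecreasing sigmoid with the declared
           midpoint", {
    inp <- g1CdkInput(amplitude = 500, midpoint = 900, sigma = 180)
    t <- seq(0, 7200, by = 10)
    a <- g1cdkActivity(t, inp)
    expect_equal(a[1], 0)
    expect_true(all(diff(a) >= 0))
    expect_lt(g1cdkActivity(0, inp), 0.01 * 500)
    expect_equal(g1cdkActivity(900, inp), 250)
    expect_equal(g1cdkActivity(1e7, inp), 500, tolerance = 1e-3)
    expect_error(g1cdkActivity(-1, inp), "t must be")
})

test_that("model construction enforces completeness and option structure", {
    m <- buildModel()
    expect_equal(stateCount(m), 20L)
    expect_equal(stateCount(buildModel(orcLayer = FALSE)), 10L)
    ## missing rate constant is named in the error
    ps <- defaultParameterSet()
    ps@params <- ps@params[ps@params$name != "kfire", ]
    expect_error(buildModel(params = ps), "kfire")
    ## negative abundance rejected
    pool <- defaultProteinPool()
    pool@counts["Cdc6"] <- -5
    expect_error(buildModel(pools = pool), "negative|counts")
})

test_that("every origin-state conversion has zero net stoichiometry over
           origin states", {
    for (opts in list(buildModel(), buildModel(orcLayer = FALSE),
                      buildModel(bindingOrder = "origin"))) {
        rl <- reactionList(opts)
        states <- unique(c(rl$from, rl$to))
        for (i in seq_len(nrow(rl))) {
            stoich <- setNames(numeric(length(states)), states)
            stoich[rl$from[i]] <- stoich[rl$from[i]] - 1
            stoich[rl$to[i]] <- stoich[rl$to[i]] + 1
            expect_equal(sum(stoich), 0)
        }
        ## every reaction cites an existing rate constant
        expect_true(all(rl$rate %in% paramTable(opts@params)$name))
    }
})

test_that("forbidden reactions are absent from the topology", {
    rl <- reactionList(buildModel())
    ## ORC phosphorylation only where ORC is exposed (S0, S1, S9): never
    ## from the Cdt1-bound state S2 nor from assembled pre-RC/pre-IC states
    for (i in 2:8)
        expect_false(any(rl$from == paste0("S", i) &
                         rl$to == paste0("S", i, "P")))
    ## no Cdt1.Mcm loading in the phosphorylated layer
    expect_false(any(rl$from == "S1P" & rl$to == "S2P"))
    ## relicensing only from the unphosphorylated fired state
    expect_false(any(rl$from == "S9P" & rl$to == "S3P"))
})
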