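test_that("origin placement accumulates sampled spacings reproducibly", {
    const <- spacingSampler(46, family = "constant")
    expect_equal(placeOrigins(const, 4), c(0, 46, 92, 138))
    s <- spacingSampler(46, 0.55)
    p1 <- placeOrigins(s, 190, seed = 9)
    p2 <- placeOrigins(s, 190, seed = 9)
    expect_identical(p1, p2)
    expect_true(all(diff(p1) > 0))
    ## sample mean spacing within 3 SE of 46 kb
    sp <- diff(placeOrigins(s, 5000, seed = 1))
    se <- sd(sp) / sqrt(length(sp))
    expect_lt(abs(mean(sp) - 46), 3 * se)
})

test_that("spacing sampler families honour mean, CV and positivity", {
    set.seed(2)
    x <- spacingSampler(46, 0.55, "gamma")(1e5)
    expect_true(all(x > 0))
    expect_equal(mean(x), 46, tolerance = 0.005)
    expect_equal(sd(x) / mean(x), 0.55, tolerance = 0.01)
    y <- spacingSampler(46, 1e-9)(100)
    expect_equal(y, rep(46, 100), tolerance = 1e-6)
    expect_error(spacingSampler(46, 0.5, "weibull"))
})

test_that("firing times are inverse-CDF samples of the density", {
    t <- seq(0, 100, by = 0.1)
    f <- stats::dnorm(t, 50, 8)
    pr <- firingProfileFromDensity(t, f)
    x <- assignFiringTimes(pr, 1e4, seed = 5, units = "s")
    ks <- suppressWarnings(stats::ks.test(x, function(q)
        stats::pnorm(q, 50, 8)))
    expect_lt(unname(ks$statistic), 0.02)
    expect_identical(x, assignFiringTimes(pr, 1e4, seed = 5, units = "s"))
    ## near-point mass: all draws at its location
    g <- ifelse(abs(t - 30) < 0.05, 1, 0)
    xs <- assignFiringTimes(firingProfileFromDensity(t, g), 50, seed = 1,
                            units = "s")
    expect_true(all(abs(xs - 30) < 0.2))
    expect_error(assignFiringTimes(firingProfileFromDensity(t, t * 0), 5),
                 "zero-mass")
})

test_that("fork-meeting geometry follows (d + v dt)/2", {
    ## two origins 100 kb apart, 10 min apart, v = 1.5 kb/min
    map <- computeReplicons(c(0, 100), c(0, 10), v = 1.5)
    expect_equal(unname(map@boundaries[1, 2]), 57.5)
    expect_equal(unname(repliconSizes(map)), c(57.5, 42.5))
    ## simultaneous firing meets at the midpoint
    map2 <- computeReplicons(c(0, 100), c(5, 5), v = 2)
    expect_equal(unname(map2@boundaries[1, 2]), 50)
    ## single fired origin replicates the whole chromosome
    map3 <- computeReplicons(100, 0, v = 2, chromLength = 200)
    expect_equal(unname(repliconSizes(map3)), 200)
    expect_equal(sPhaseLength(map3), 200 / (2 * 2))
})

test_that("passive replication is detected and sizes still tile the
           chromosome", {
    ## 10 kb apart, 6 min late, v = 2: fork arrives after 5 min < 6 min
    map <- computeReplicons(c(0, 10), c(0, 6), v = 2, chromLength = 20)
    expect_equal(map@status, c("fired", "passive"))
    expect_equal(sum(repliconSizes(map)), 20)
    expect_equal(passiveFraction(c(0, 10), c(0, 6), v = 2), 0.5)
    ## simultaneous firing: nobody is passive
    expect_equal(passiveFraction(0:5 * 40, rep(1, 6)), 0)
})

test_that("coverage tiles exactly for random configurations", {
    set.seed(31)
    for (rep in 1:20) {
        n <- sample(3:40, 1)
        pos <- placeOrigins(spacingSampler(46, 0.55), n)
        tim <- runif(n, 0, 60)
        map <- computeReplicons(pos, tim, v = 1.5)
        expect_lt(abs(sum(repliconSizes(map)) - map@chromLength), 1e-6)
        ## every passive origin is reached by a fork before its firing time
        pas <- which(map@status == "passive")
        for (i in pas) {
            d <- abs(pos[-i] - pos[i])
            expect_true(min(tim[-i] + d / 1.5) < tim[i])
        }
    }
})

test_that("equally spaced simultaneous origins give S phase s/(2v)", {
    pos <- seq(0, 400, by = 40)
    map <- computeReplicons(pos, rep(0, length(pos)), v = 1.6)
    expect_equal(sPhaseLength(map), 40 / (2 * 1.6))
})

test_that("mean-preserving spread of firing times cannot reduce passive
           replication", {
    set.seed(77)
    pos <- placeOrigins(spacingSampler(46, 0.55), 150)
    base <- rnorm(150, 50, 2)
    pfs <- vapply(c(1, 3, 6, 12), function(scale) {
        tim <- 50 + (base - 50) * scale    # widen around the same mean
        passiveFraction(pos, tim, v = 1.5)
    }, 0)
    expect_true(all(diff(pfs) >= 0))
})

test_that("replicon summary and BED-like table are consistent", {
    pos <- c(0, 50, 120); tim <- c(0, 2, 40)
    map <- computeReplicons(pos, tim, v = 1.5, chromLength = 150)
    tab <- repliconTable(map)
    expect_equal(nrow(tab), 3)
    expect_equal(tab$status, map@status)
    sm <- repliconSummary(map)
    expect_equal(sm$nFired + sum(map@status == "passive"), 3)
    expect_equal(sm$meanSizeKb, mean(repliconSizes(map)))
})
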