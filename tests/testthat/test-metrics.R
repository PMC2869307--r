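test_that("profile statistics reproduce closed forms for simple densities", {
    t <- seq(0, 1000, by = 0.5)
    ## uniform density on [a, b]: tau = (a+b)/2, Delta = 2 w / sqrt(12)
    a <- 200; b <- 600; w <- b - a
    f <- ifelse(t >= a & t <= b, 1 / w, 0) * 0.9   # mass 0.9 per origin
    pr <- firingProfileFromDensity(t, f, M = 190)
    expect_equal(totalFirings(pr), 190 * 0.9, tolerance = 5e-3)
    expect_equal(meanFiringTime(pr), (a + b) / 2, tolerance = 1e-3)
    expect_equal(firingDuration(pr), 2 * w / sqrt(12), tolerance = 5e-3)
    ## narrow pulse at t0: tau = t0, Delta -> 0
    t0 <- 400
    g <- exp(-(t - t0)^2 / (2 * 4))
    g <- g / trapzNum(t, g)
    prg <- firingProfileFromDensity(t, g, M = 190)
    expect_equal(meanFiringTime(prg), t0, tolerance = 1e-6)
    expect_lt(firingDuration(prg), 5)
})

test_that("Delta is shift-invariant and scale-covariant with tau", {
    t <- seq(0, 2000, by = 1)
    f <- stats::dgamma(t, shape = 5, scale = 60)
    p0 <- firingProfileFromDensity(t, f)
    ## shift by 300 s
    f2 <- c(numeric(300), f[1:(length(f) - 300)])
    p1 <- firingProfileFromDensity(t, f2)
    expect_equal(firingDuration(p1), firingDuration(p0), tolerance = 1e-2)
    expect_equal(meanFiringTime(p1), meanFiringTime(p0) + 300,
                 tolerance = 1e-2)
    ## rescale time by c = 2
    p2 <- firingProfileFromDensity(2 * t, f / 2)
    expect_equal(meanFiringTime(p2), 2 * meanFiringTime(p0),
                 tolerance = 1e-6)
    expect_equal(firingDuration(p2), 2 * firingDuration(p0),
                 tolerance = 1e-6)
})

test_that("zero-mass profiles are flagged", {
    pr <- firingProfileFromDensity(0:10, numeric(11))
    expect_equal(totalFirings(pr), 0)
    expect_warning(expect_true(is.na(meanFiringTime(pr))), "zero total")
    expect_warning(expect_true(is.na(firingDuration(pr))), "zero total")
})

test_that("firing rate equals the derivative of cumulative firing on a
           trajectory", {
    tr <- simulateModel(buildModel(params = refParams()), dt = 10)
    cum <- tr@states[, "cumFire"]
    f <- firingFlux(tr)
    mid <- diff(cum) / diff(tr@time)
    favg <- (head(f, -1) + tail(f, -1)) / 2
    expect_lt(max(abs(mid - favg)) / max(f), 2e-2)
    ## trapezoid N agrees with the exact accumulator
    pr <- firingProfile(tr)
    expect_equal(totalFirings(pr), 190 * cum[length(cum)],
                 tolerance = 1e-4)
    ## cumulative firing is monotone
    expect_true(all(diff(cum) > -1e-12))
})

test_that("rho from paired simulations is nonnegative, zero when the gate
           is closed, and matches the metrics record", {
    ps <- refParams()
    rr <- rereplicationCount(params = ps)
    expect_gte(rr$rho, 0)
    expect_equal(rr$N - rr$N0, rr$rho, tolerance = 1e-9)
    ps0 <- setParamValues(ps, c(k16 = 0))
    rr0 <- rereplicationCount(params = ps0)
    expect_equal(rr0$rho, 0, tolerance = 1e-6)
})
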