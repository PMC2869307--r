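test_that("chain state counts match the collapsed representation", {
    expect_equal(chainStates(buildChain(6, finalSite = TRUE)), 8L)   # Sld2
    expect_equal(chainStates(buildChain(2)), 3L)                     # Sld3
    expect_equal(chainStates(buildChain(0, finalSite = TRUE)), 2L)   # switch
    expect_error(buildChain(-1), "nRandom")
})

test_that("all mass starts unphosphorylated and stays normalized", {
    ch <- buildChain(4, finalSite = TRUE, kcat = 0.01, Km = 1, kp = 0.002)
    occ <- chainOccupancy(ch, 1, seq(0, 2000, by = 10))
    expect_equal(unname(occ[1, "j0"]), 1)
    tot <- rowSums(occ[, c(paste0("j", 0:4), "final")])
    expect_lt(max(abs(tot - 1)), 1e-7)
})

test_that("irreversible 6-site chain completes in H6/k time, matching a
           max-of-exponentials oracle", {
    k <- 0.01
    ch <- buildChain(6, kcat = k, Km = 1)      # per-site rate k
    cs <- completionStats(ch, 1)
    H6 <- sum(1 / (1:6))
    expect_equal(cs$tau, H6 / k, tolerance = 1e-3)   # 245 s
    ## completion time of n parallel sites = max of 6 iid Exp(k)
    set.seed(42)
    oracle <- replicate(4000, max(rexp(6, k)))
    se <- sd(oracle) / sqrt(length(oracle))
    expect_lt(abs(cs$tau - mean(oracle)), 3 * se)
})

test_that("single-site chain has exponential completion moments", {
    k <- 0.02
    cs <- completionStats(buildChain(1, kcat = k, Km = 1), 1)
    expect_equal(cs$tau, 1 / k, tolerance = 1e-3)
    expect_equal(cs$coherence, 2, tolerance = 1e-3)  # Delta = 2 sd = 2/k
})

test_that("the hierarchical final site rises with a delay, unlike the
           processive variant", {
    times <- seq(0, 1500, by = 5)
    ch <- buildChain(6, finalSite = TRUE, kcat = 0.01, Km = 1)
    occ <- chainOccupancy(ch, 1, times)
    halfRise <- function(y) times[which(y >= 0.5 * max(y))[1]]
    expect_gt(halfRise(occ[, "final"]), halfRise(occ[, "siteMarginal"]))
    ## processive: one encounter phosphorylates everything, no extra delay
    pro <- buildChain(6, finalSite = TRUE, kcat = 0.01, Km = 1,
                      processive = TRUE)
    occp <- chainOccupancy(pro, 1, times)
    expect_equal(halfRise(occp[, "complete"]),
                 halfRise(occp[, "siteMarginal"]))
})

test_that("completion time grows sublinearly and coherence improves with
           site number", {
    stats <- lapply(1:7, function(n)
        completionStats(buildChain(n, kcat = 0.01, Km = 1), 1))
    tau <- vapply(stats, `[[`, 0, "tau")
    coh <- vapply(stats, `[[`, 0, "coherence")
    expect_true(all(diff(tau) > 0))          # monotone increase
    expect_true(all(diff(coh) < 0))          # increasing temporal coherence
    ## H_n growth: tau(2n) < 2 tau(n)
    expect_lt(tau[6], 2 * tau[3])
    expect_lt(tau[4], 2 * tau[2])
})

test_that("collapsed chain equals the full 2^n microstate model", {
    k <- 0.008; kp <- 0.003
    for (n in 2:4) {
        ch <- buildChain(n, kcat = k, Km = 1, kp = kp)
        times <- seq(0, 600, by = 20)
        occ <- chainOccupancy(ch, 1, times)
        ## full microstate master equation over binary site patterns
        nm <- 2^n
        rhs <- function(t, y, p) {
            dy <- numeric(nm)
            for (s in 0:(nm - 1)) for (b in 0:(n - 1)) {
                on <- bitwAnd(s, bitwShiftL(1L, b)) > 0
                partner <- bitwXor(s, bitwShiftL(1L, b))
                if (!on) {                    # phosphorylation s -> s|b
                    v <- k * y[s + 1]
                    dy[s + 1] <- dy[s + 1] - v
                    dy[partner + 1] <- dy[partner + 1] + v
                } else {                      # dephosphorylation s -> s&~b
                    v <- kp * y[s + 1]
                    dy[s + 1] <- dy[s + 1] - v
                    dy[partner + 1] <- dy[partner + 1] + v
                }
            }
            list(dy)
        }
        out <- deSolve::ode(c(1, numeric(nm - 1)), times, rhs, NULL,
                            rtol = 1e-10, atol = 1e-12)
        bits <- vapply(0:(nm - 1), function(s)
            sum(bitwAnd(s, bitwShiftL(1L, 0:(n - 1))) > 0), 0)
        for (j in 0:n) {
            full <- rowSums(out[, 1 + which(bits == j), drop = FALSE])
            expect_lt(max(abs(full - occ[, paste0("j", j)])), 1e-8)
        }
    }
})

test_that("without phosphatase the terminal state absorbs all mass", {
    ch <- buildChain(3, finalSite = TRUE, kcat = 0.05, Km = 1)
    occ <- chainOccupancy(ch, 1, seq(0, 3000, by = 50))
    expect_gt(occ[nrow(occ), "final"], 0.999)
})

test_that("multisite output coherence is decoupled from the kinase
           switch-on time, single-site is not", {
    ch <- buildChain(6, finalSite = TRUE, kcat = 0.01, Km = 1)
    dec <- inputDecoupling(ch, sigmas = c(30, 120, 480))
    ## single-site coherence degrades steadily with slower input
    expect_true(all(diff(dec$coherenceSingle) > 0))
    expect_gt(dec$coherenceSingle[3] / dec$coherenceSingle[1], 2)
    ## multisite stays within a factor 2 over the same range
    expect_lt(max(dec$coherence) / min(dec$coherence), 2)
    ## step-input limit: both coherent, multisite slower
    expect_gt(dec$tau[1], dec$tauSingle[1])
    expect_lt(dec$coherence[1], 1.2)
})
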