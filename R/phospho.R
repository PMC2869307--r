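#' Build a random-sequential distributive phosphorylation chain
#'
#' The chain tracks the number j = 0..n of phosphorylated random sites
#' (identical per-site kinetics make the collapsed representation exact) and,
#' optionally, a hierarchical final site that becomes available only at
#' j = n -- the Thr84-like docking site.  Per-site phosphorylation proceeds
#' at hazard h(t) = kcat E(t) / (Km + ctot), i.e. Michaelis-Menten kinetics
#' evaluated at the (constant) total substrate concentration, which keeps the
#' collapsed dynamics linear; with ctot = 0 and E = 1 the per-site rate is
#' simply kcat/Km.  The multiplicity of unphosphorylated sites scales the
#' forward rate ((n - j) h) and of phosphorylated sites the phosphatase rate
#' (j kp).
#'
#' @param nRandom number of symmetric random sites (>= 0).
#' @param finalSite add the hierarchical final site (default FALSE).
#' @param kcat,Km per-site kinase turnover (1/s) and Michaelis constant.
#' @param kp per-site dephosphorylation rate, 1/s (default 0).
#' @param kcatFinal,KmFinal final-site kinetics (default: same as random).
#' @param ctot substrate concentration in the saturation term (default 0).
#' @param processive single-encounter variant: one kinase encounter
#'   phosphorylates every site at once (comparison fixture).
#' @return A [PhosphoChain-class] object.
#' @export
buildChain <- function(nRandom, finalSite = FALSE, kcat = 0.01, Km = 1,
                       kp = 0, kcatFinal = kcat, KmFinal = Km, ctot = 0,
                       processive = FALSE) {
    if (nRandom < 0) stop("nRandom must be >= 0")
    stopifnot(kcat > 0, Km > 0, kp >= 0)
    new("PhosphoChain", nRandom = as.numeric(nRandom), finalSite = finalSite,
        kcat = kcat, Km = Km, kcatFinal = kcatFinal, KmFinal = KmFinal,
        kp = kp, ctot = ctot, processive = processive)
}

#' Number of collapsed states of a chain
#' @param chain PhosphoChain.
#' @export
chainStates <- function(chain) {
    if (chain@processive) return(2L)
    as.integer(chain@nRandom + 1 + chain@finalSite)
}

.chainKinase <- function(kinase) {
    if (is.function(kinase)) kinase else function(t) rep(kinase, length(t))
}

## linear generator of the collapsed chain at kinase activity e
.chainRates <- function(chain, e) {
    n <- chain@nRandom
    h <- chain@kcat * e / (chain@Km + chain@ctot)
    hf <- chain@kcatFinal * e / (chain@KmFinal + chain@ctot)
    list(h = h, hf = hf, n = n, kp = chain@kp)
}

#' Occupancy time course of a phosphorylation chain
#'
#' Integrates the collapsed master equation under a (possibly time-varying)
#' kinase activity, starting with all mass in the unphosphorylated state.
#'
#' @param chain PhosphoChain.
#' @param kinase kinase activity: a constant or a function of time (seconds).
#' @param times output time grid, seconds.
#' @return matrix of occupancies; columns j0..jn (and "final" if present),
#'   plus column "siteMarginal", the per-site phosphorylation probability of
#'   a random site.
#' @export
chainOccupancy <- function(chain, kinase, times) {
    E <- .chainKinase(kinase)
    n <- chain@nRandom
    if (chain@processive) {
        rhs <- function(t, y, p) {
            h <- chain@kcat * E(t) / (chain@Km + chain@ctot)
            list(c(-h * y[1], h * y[1]))
        }
        out <- deSolve::ode(c(1, 0), times, rhs, NULL, method = "lsoda",
                            rtol = 1e-10, atol = 1e-12)
        occ <- out[, -1, drop = FALSE]
        colnames(occ) <- c("j0", "complete")
        return(cbind(occ, siteMarginal = occ[, "complete"]))
    }
    ns <- chainStates(chain)
    rhs <- function(t, y, p) {
        r <- .chainRates(chain, E(t))
        dy <- numeric(ns)
        for (j in 0:(n - 1)) {            # random-site ladder
            if (n == 0) break
            v <- (n - j) * r$h * y[j + 1]
            dy[j + 1] <- dy[j + 1] - v; dy[j + 2] <- dy[j + 2] + v
        }
        if (chain@kp > 0 && n > 0) for (j in 1:n) {
            v <- j * r$kp * y[j + 1]
            dy[j + 1] <- dy[j + 1] - v; dy[j] <- dy[j] + v
        }
        if (chain@finalSite) {
            v <- r$hf * y[n + 1]
            dy[n + 1] <- dy[n + 1] - v; dy[ns] <- dy[ns] + v
            if (chain@kp > 0) {
                v <- r$kp * y[ns]
                dy[ns] <- dy[ns] - v; dy[n + 1] <- dy[n + 1] + v
            }
        }
        list(dy)
    }
    y0 <- c(1, numeric(ns - 1))
    out <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    occ <- out[, -1, drop = FALSE]
    colnames(occ) <- c(paste0("j", 0:n), if (chain@finalSite) "final")
    marg <- if (n > 0) {
        occ[, paste0("j", 0:n), drop = FALSE] %*% (0:n / n) +
            (if (chain@finalSite) occ[, "final"] else 0)
    } else if (chain@finalSite) occ[, "final"] else rep(0, nrow(occ))
    cbind(occ, siteMarginal = as.numeric(marg))
}

## flux into the terminal state (kinase direction only)
.terminalFlux <- function(chain, kinase, times) {
    occ <- chainOccupancy(chain, kinase, times)
    E <- .chainKinase(kinase)
    n <- chain@nRandom
    if (chain@processive)
        return(chain@kcat * E(times) / (chain@Km + chain@ctot) * occ[, "j0"])
    if (chain@finalSite) {
        chain@kcatFinal * E(times) / (chain@KmFinal + chain@ctot) *
            occ[, paste0("j", n)]
    } else {
        1 * chain@kcat * E(times) / (chain@Km + chain@ctot) *
            occ[, paste0("j", n - 1)]
    }
}

#' Completion statistics of a phosphorylation chain
#'
#' Mean completion time tau_p (first moment of the flux into the terminal,
#' fully phosphorylated state) and completion duration Delta_p (twice its
#' standard deviation), computed on an automatically extended horizon.
#'
#' @param chain PhosphoChain.
#' @param kinase kinase activity (constant or function of time).
#' @param horizon initial horizon in seconds (extended until >= 99.9% of the
#'   chain has completed, up to maxHorizon).
#' @param maxHorizon horizon cap, seconds.
#' @param nGrid grid points.
#' @return list(tau, delta, coherence = delta/tau, completed, terminalMass).
#' @export
completionStats <- function(chain, kinase, horizon = NULL,
                            maxHorizon = 1e7, nGrid = 2000) {
    E <- .chainKinase(kinase)
    if (is.null(horizon)) {
        e1 <- max(E(c(1, 10, 100, 1000, 1e4)), 1e-12)
        h <- chain@kcat * e1 / (chain@Km + chain@ctot)
        horizon <- 50 * (chain@nRandom + 1) / h
    }
    repeat {
        times <- seq(0, horizon, length.out = nGrid)
        occ <- chainOccupancy(chain, kinase, times)
        termCol <- if (chain@processive) "complete" else
            if (chain@finalSite) "final" else paste0("j", chain@nRandom)
        term <- occ[nrow(occ), termCol]
        if (term >= 0.999 || horizon >= maxHorizon) break
        horizon <- horizon * 2
    }
    flux <- .terminalFlux(chain, kinase, times)
    m0 <- .trapz(times, flux)
    if (m0 <= 1e-6)
        return(list(tau = NA_real_, delta = NA_real_, coherence = NA_real_,
                    completed = FALSE, terminalMass = unname(term)))
    m1 <- .trapz(times, times * flux) / m0
    m2 <- .trapz(times, times^2 * flux) / m0
    delta <- 2 * sqrt(max(m2 - m1^2, 0))
    list(tau = m1, delta = delta, coherence = delta / m1,
         completed = term >= 0.99, terminalMass = unname(term))
}

#' Coherence of chain output versus kinase switch-on time
#'
#' For each input time scale sigma the kinase rises as a Hill-in-time
#' sigmoid with a fixed midpoint and Hill exponent midpoint/sigma (the same
#' family as the network's G1-Cdk input; sigma -> 0 approaches a step at the
#' midpoint, large sigma a piecemeal rise), and the output coherence
#' Delta_p/tau_p of the chain is compared with a single-site switch with the
#' same per-site kinetics.  The default sigma grid spans up to about twice
#' the intrinsic completion time of the default chain; for much slower
#' inputs any module simply mirrors the input kinetics.
#'
#' @param chain PhosphoChain.
#' @param sigmas vector of input switch-on times, seconds.
#' @param midpoint input activation midpoint, seconds (default 900).
#' @param emax maximal kinase activity (default 1).
#' @return data.frame with sigma, coherence (Delta_p/tau_p) of the chain and
#'   of the single-site reference, plus both tau values.
#' @export
inputDecoupling <- function(chain, sigmas = c(30, 60, 120, 240, 480),
                            midpoint = 900, emax = 1) {
    single <- buildChain(0, finalSite = TRUE, kcat = chain@kcat,
                         Km = chain@Km, kcatFinal = chain@kcatFinal,
                         KmFinal = chain@KmFinal, ctot = chain@ctot)
    res <- lapply(sigmas, function(s) {
        h <- midpoint / s
        kin <- function(t)
            ifelse(t <= 0, 0, emax * t^h / (t^h + midpoint^h))
        cs <- completionStats(chain, kin)
        c1 <- completionStats(single, kin)
        data.frame(sigma = s, coherence = cs$coherence,
                   coherenceSingle = c1$coherence,
                   tau = cs$tau, tauSingle = c1$tau)
    })
    do.call(rbind, res)
}
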