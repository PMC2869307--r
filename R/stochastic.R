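## Per-origin stochastic simulation: the free-protein concentrations are
## taken from the deterministic trajectory (their copy-number fluctuations
## are negligible at thousands of molecules), while each origin performs a
## continuous-time Markov jump process over the 20 origin states.  Events
## are generated exactly by Lewis thinning against a piecewise majorant of
## the time-varying transition rates.

.originTransitions <- function(model, traj) {
    p <- model@parms
    Cori <- p[["Cori"]]
    gv <- function(nm) approxfun(traj@time, traj@states[, nm], rule = 2)
    C6 <- gv("Cdc6"); CM <- gv("Cdt1Mcm"); C45 <- gv("Cdc45")
    Tt <- gv("Activator"); GP <- gv("GINSPol"); SC <- gv("SCdk")
    D3 <- gv("Dpb11pSld3"); p2 <- gv("pSld2")
    occ <- lapply(.originStateNames, gv)
    names(occ) <- .originStateNames
    variant <- p[["bindVariant"]] > 0
    trans <- list()
    add <- function(from, to, fn)
        trans[[length(trans) + 1L]] <<- list(from = from, to = to, rate = fn)
    mmO <- function(kcat, Km, e, s, st)     # kinase acting on origin state st
        function(t) kcat * e(t) * 1 / (Km + Cori * pmax(occ[[st]](t), 0))
    for (L in c("", "P")) {
        s <- function(i) paste0("S", i, L)
        add(s(0), s(1), function(t) p[["kon6"]] * pmax(C6(t), 0))
        add(s(1), s(0), function(t) rep(p[["koff6"]], length(t)))
        if (L == "") {
            add("S1", "S2", function(t) p[["konL"]] * pmax(CM(t), 0))
            add("S2", "S1", function(t) rep(p[["koffL"]], length(t)))
            add("S2", "S3", function(t) rep(p[["kload"]], length(t)))
        }
        add(s(3), s(4), local({st <- s(3)
            function(t) p[["kcatMcm"]] * (pmax(SC(t), 0) + p[["Ddk"]]) /
                (p[["KmMcm"]] + Cori * pmax(occ[[st]](t), 0))}))
        add(s(4), s(5), function(t) p[["kon45"]] * pmax(C45(t), 0))
        add(s(5), s(4), function(t) rep(p[["koff45"]], length(t)))
        if (!variant) {
            add(s(5), s(6), function(t) p[["konT"]] * pmax(Tt(t), 0))
            add(s(6), s(5), function(t) rep(p[["koffT"]], length(t)))
            add(s(6), s(7), function(t) p[["konGPo"]] * pmax(GP(t), 0))
            add(s(7), s(6), function(t) rep(p[["koffGPo"]], length(t)))
        } else {
            add(s(5), s(6), function(t) p[["konT"]] * pmax(D3(t), 0))
            add(s(6), s(5), function(t) rep(p[["koffT"]], length(t)))
            kd2 <- if (p[["konD2"]] > 0) p[["koffD2"]] / p[["konD2"]] else 1e-6
            add(s(6), s(7), function(t) {
                x <- pmax(p2(t), 0)
                p[["konGPo"]] * pmax(GP(t), 0) * x / (x + kd2)
            })
        }
        add(s(7), s(8), function(t) rep(p[["krel"]], length(t)))
        add(s(8), s(9), function(t) rep(p[["kfire"]], length(t)))
    }
    if (p[["orcLayer"]] > 0)
        for (i in c(0, 1, 9)) {
            st <- paste0("S", i)
            add(st, paste0("S", i, "P"), local({st0 <- st
                function(t) p[["kcatOrc"]] * pmax(SC(t), 0) /
                    (p[["KmOrc"]] + Cori * pmax(occ[[st0]](t), 0))}))
        }
    if (p[["k16"]] > 0) {
        Kav <- p[["Kavail"]]
        add("S9", "S3", function(t) {
            c6 <- pmax(C6(t), 0); cm <- pmax(CM(t), 0)
            p[["k16"]] * c6 / (c6 + Kav) * cm / (cm + Kav)
        })
    }
    trans
}

#' Stochastic per-origin simulation
#'
#' Simulates n independent origins as continuous-time Markov chains over the
#' origin states, with transition propensities driven by the deterministic
#' free-protein concentrations of the mean-field trajectory.  Event times are
#' exact (thinning against a piecewise-constant majorant of each rate with a
#' safety factor; a warning is raised if the majorant is ever exceeded).
#'
#' @param model ReplicationModel.
#' @param nOrigins number of origins to simulate (>= 1).
#' @param horizon horizon in seconds.
#' @param seed RNG seed; the same seed reproduces the identical event log.
#' @param traj optional precomputed deterministic Trajectory of the model.
#' @param dt grid spacing for the deterministic run if traj is NULL.
#' @param maxEvents cap on the total number of logged events (rapidly
#'   bouncing reversible bindings can generate enormous logs); the
#'   simulation stops with a warning when the cap is reached.
#' @return data.frame event log with columns origin, time, from, to.
#' @export
stochasticSimulate <- function(model, nOrigins, horizon = 10800, seed = 1,
                               traj = NULL, dt = 20, maxEvents = 1e6) {
    stopifnot(nOrigins >= 1)
    if (is.null(traj)) traj <- simulateModel(model, horizon = horizon, dt = dt)
    trans <- .originTransitions(model, traj)
    from <- vapply(trans, `[[`, "", "from")
    byState <- split(seq_along(trans), from)
    grid <- seq(0, horizon, length.out = 257)
    w <- diff(grid)[1]
    ## per-transition majorant on each grid cell (interval max x margin)
    maj <- lapply(trans, function(tr) {
        r <- tr$rate(grid)
        if (any(r < -1e-12)) stop("negative propensity")
        m <- pmax(head(r, -1), tail(r, -1)) * 1.5 + 1e-12
        cummaxed <- m   # piecewise majorant per cell
        cummaxed
    })
    set.seed(seed)
    cap <- as.integer(maxEvents)
    evOrigin <- integer(cap); evTime <- numeric(cap)
    evTrans <- integer(cap); ne <- 0L
    capped <- FALSE
    for (o in seq_len(nOrigins)) {
        t <- 0; st <- "S0"
        while (t < horizon) {
            idx <- byState[[st]]
            if (is.null(idx)) break
            cell <- min(floor(t / w) + 1, length(grid) - 1)
            M <- sum(vapply(idx, function(i) maj[[i]][cell], 0))
            if (M <= 1e-300) { t <- grid[cell + 1] + 1e-9; next }
            tprop <- t + rexp(1, M)
            if (tprop > grid[cell + 1]) { t <- grid[cell + 1] + 1e-12; next }
            rts <- vapply(idx, function(i) trans[[i]]$rate(tprop), 0)
            if (sum(rts) > M * 1.0001)
                warning("rate majorant exceeded; event intensity clipped")
            t <- tprop
            if (runif(1) <= sum(rts) / M) {
                i <- idx[sample.int(length(idx), 1, prob = rts)]
                ne <- ne + 1L
                if (ne > cap) { capped <- TRUE; break }
                evOrigin[ne] <- o; evTime[ne] <- t; evTrans[ne] <- i
                st <- trans[[i]]$to
            }
        }
        if (capped) break
    }
    if (capped) {
        ne <- cap
        warning("event cap reached (maxEvents = ", cap,
                "); log truncated at origin ", o)
    }
    keep <- seq_len(ne)
    data.frame(origin = evOrigin[keep], time = evTime[keep],
               from = vapply(trans, `[[`, "", "from")[evTrans[keep]],
               to = vapply(trans, `[[`, "", "to")[evTrans[keep]],
               stringsAsFactors = FALSE)
}

#' Stochastic simulation of a constant-rate linear chain
#'
#' Gillespie simulation of n independent units on a linear chain of states
#' with constant forward rates; used as an independent oracle for mean-field
#' first-passage times.
#'
#' @param rates vector of forward rates (state i -> i+1), 1/s.
#' @param nUnits number of units.
#' @param seed RNG seed.
#' @return numeric vector of first-passage times to the terminal state.
#' @export
stochasticChain <- function(rates, nUnits, seed = 1) {
    set.seed(seed)
    colSums(matrix(rexp(nUnits * length(rates), rate = rates),
                   nrow = length(rates)))
}
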