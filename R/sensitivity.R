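#' Relative control coefficient of a scalar response
#'
#' Central finite difference on logarithmically perturbed input:
#' C = dln R / dln X evaluated with relative step `step`, together with the
#' two one-sided estimates for convergence diagnosis.  Responses crossing
#' zero are floored at `floor` before taking logs.
#'
#' @param fn function(x) returning the scalar response R(x).
#' @param x0 base value (> 0).
#' @param step relative perturbation (default 0.05).
#' @param floor additive floor applied to the response (default 1e-6).
#' @return list(C, up, down, R0) with the central and one-sided estimates.
#' @export
controlCoefficient <- function(fn, x0, step = 0.05, floor = 1e-6) {
    stopifnot(x0 > 0, step > 0, step < 1)
    r0 <- fn(x0); rp <- fn(x0 * (1 + step)); rm <- fn(x0 * (1 - step))
    g <- function(r) log(max(r, 0) + floor)
    up   <- (g(rp) - g(r0)) / log(1 + step)
    down <- (g(r0) - g(rm)) / -log(1 - step)
    C <- (g(rp) - g(rm)) / (log(1 + step) - log(1 - step))
    list(C = C, up = up, down = down, R0 = r0)
}

#' Euclidean norm of a control-coefficient vector
#' @param v numeric vector of coefficients (NAs dropped).
#' @export
sensitivityNorm <- function(v) sqrt(sum(v[is.finite(v)]^2))

## evaluate all four responses (N, tau, Delta, rho) for given pools/params
.responses <- function(params, pools, horizon, dt, rtol, ...) {
    ev <- evaluateCandidate(params, pools, horizon = horizon, dt = dt,
                            rtol = rtol, ...)
    if (!ev$ok) return(c(N = NA, tau = NA, Delta = NA, rho = NA))
    c(N = ev$N, tau = ev$tau_min, Delta = ev$Delta_min, rho = ev$rho)
}

#' Control coefficients of the network responses
#'
#' Computes C_X^R = (X/R) dR/dX for R in {N, tau, Delta, rho} with respect
#' to one protein concentration or one kinetic parameter, by central finite
#' differences on a +/- `step` relative perturbation.  A protein absent from
#' the network model yields exactly zero coefficients.
#'
#' @param quantity name of a protein (in the pool) or rate constant.
#' @param params ParameterSet of the (admissible) base point.
#' @param pools ProteinPool.
#' @param step relative perturbation (default 0.05).
#' @param rhoFloor additive floor for the rho response (default 1e-6
#'   origins, to keep log-derivatives finite when rho is near machine zero).
#' @param horizon,dt,rtol solver settings.
#' @param ... structural options for [buildModel()].
#' @return data.frame with one row per response: C, up, down, R0.
#' @export
networkControl <- function(quantity, params, pools = defaultProteinPool(),
                           step = 0.05, rhoFloor = 1e-6,
                           horizon = 10800, dt = 30, rtol = 1e-6, ...) {
    isProt <- quantity %in% names(pools@counts)
    isPar <- quantity %in% params@params$name
    if (!isProt && !isPar) stop("unknown quantity: ", quantity)
    base <- if (isProt) poolCount(pools, quantity) else
        paramValue(params, quantity)
    if (base <= 0) stop("base value of ", quantity, " must be > 0")
    perturbed <- function(x) {
        if (isProt) .responses(params, setPoolCounts(pools,
            setNames(x, quantity)), horizon, dt, rtol, ...)
        else .responses(setParamValues(params, setNames(x, quantity),
            check = FALSE), pools, horizon, dt, rtol, ...)
    }
    r0 <- perturbed(base)
    rp <- perturbed(base * (1 + step))
    rm <- perturbed(base * (1 - step))
    res <- lapply(names(r0), function(resp) {
        fl <- if (resp == "rho") rhoFloor else 0
        g <- function(r) log(max(r, 0) + fl)
        if (anyNA(c(r0[resp], rp[resp], rm[resp])) ||
            (fl == 0 && min(r0[resp], rp[resp], rm[resp]) <= 0))
            return(data.frame(response = resp, C = NA, up = NA, down = NA,
                              R0 = r0[[resp]]))
        data.frame(response = resp,
                   C = (g(rp[resp]) - g(rm[resp])) /
                       (log(1 + step) - log(1 - step)),
                   up = (g(rp[resp]) - g(r0[resp])) / log(1 + step),
                   down = (g(r0[resp]) - g(rm[resp])) / -log(1 - step),
                   R0 = r0[[resp]])
    })
    out <- do.call(rbind, res)
    out$quantity <- quantity
    out
}

#' Control-coefficient sweep over an ensemble
#'
#' For each admissible ensemble member and each quantity, computes the four
#' response coefficients and aggregates mean and standard deviation across
#' the ensemble, plus the per-response sensitivity norms.
#'
#' @param ensemble AdmissibleEnsemble.
#' @param quantities character vector of protein or parameter names.
#' @param pools ProteinPool.
#' @param ... forwarded to [networkControl()].
#' @return list(table = aggregated data.frame, norms = per-member,
#'   per-response norm matrix, failures = count of failed member
#'   evaluations).
#' @export
sensitivitySweep <- function(ensemble, quantities,
                             pools = defaultProteinPool(), ...) {
    stopifnot(length(ensemble@members) > 0)
    fails <- 0L
    per <- list()
    for (m in seq_along(ensemble@members)) {
        rows <- try(do.call(rbind, lapply(quantities, networkControl,
                                          params = ensemble@members[[m]],
                                          pools = pools, ...)),
                    silent = TRUE)
        if (inherits(rows, "try-error")) { fails <- fails + 1L; next }
        rows$member <- m
        per[[length(per) + 1L]] <- rows
    }
    if (!length(per)) stop("all ensemble members failed")
    all <- do.call(rbind, per)
    agg <- do.call(rbind, lapply(split(all, list(all$quantity, all$response),
                                       drop = TRUE), function(d)
        data.frame(quantity = d$quantity[1], response = d$response[1],
                   meanC = mean(d$C, na.rm = TRUE),
                   sdC = if (nrow(d) > 1) sd(d$C, na.rm = TRUE) else 0)))
    rownames(agg) <- NULL
    norms <- do.call(rbind, lapply(split(all, all$member), function(d)
        vapply(split(d$C, d$response), sensitivityNorm, 0)))
    list(table = agg, norms = norms, failures = fails)
}
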