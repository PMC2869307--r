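#' Default protein abundances per nucleus
#'
#' Molecule counts emulating the measured abundance pattern in budding yeast:
#' stably bound replisome factors (Mcm2-7, Cdc45, GINS) at a few thousand
#' copies, transient factors (Sld2, Dpb11, S-Cdk cyclins) at a few hundred,
#' and the notably scarce Sld3 at about 130 molecules.  Counts other than Sld3
#' are reconstructions consistent with that stable/transient dichotomy; all
#' are overridable.  The nuclear volume of 2e-15 L converts one molecule to
#' about 0.83 nM.
#'
#' @param overrides optional named numeric vector of replacement counts.
#' @return A [ProteinPool-class] object.
#' @examples
#' poolCount(defaultProteinPool(), "Sld3")   # 130
#' @export
defaultProteinPool <- function(overrides = NULL) {
    counts <- c(Cdc6 = 600, Cdt1 = 600, Mcm = 4000, Cdc45 = 3000,
                GINS = 3000, Pol = 2000, Sld2 = 400, Sld3 = 130,
                Dpb11 = 400, SCdk = 600, Sic1 = 800, G1Cdk = 500,
                Ddk = 400, Phosphatase = 500)
    if (!is.null(overrides)) {
        bad <- setdiff(names(overrides), names(counts))
        if (length(bad)) stop("unknown protein: ", paste(bad, collapse = ", "))
        counts[names(overrides)] <- overrides
    }
    new("ProteinPool", counts = counts, volume = 2e-15)
}

#' Molecule count of a protein
#' @param pool ProteinPool.
#' @param name protein name(s).
#' @export
poolCount <- function(pool, name) {
    i <- match(name, names(pool@counts))
    if (anyNA(i)) stop("unknown protein: ",
                       paste(name[is.na(i)], collapse = ", "))
    pool@counts[i]
}

#' Convert molecule counts to molar concentration
#' @param count molecule count(s).
#' @param volume nuclear volume in litres.
#' @export
countToMolar <- function(count, volume = 2e-15) count / (AVOGADRO * volume)

#' Convert molar concentration to molecule counts
#' @param conc molar concentration(s).
#' @param volume nuclear volume in litres.
#' @export
molarToCount <- function(conc, volume = 2e-15) conc * AVOGADRO * volume

#' Concentration of a pooled protein in molar
#' @param pool ProteinPool.
#' @param name protein name(s).
#' @export
poolConcentration <- function(pool, name)
    countToMolar(poolCount(pool, name), pool@volume)

#' Replace molecule counts in a pool
#' @param pool ProteinPool.
#' @param counts named numeric vector of replacement counts.
#' @return modified ProteinPool.
#' @export
setPoolCounts <- function(pool, counts) {
    i <- match(names(counts), names(pool@counts))
    if (anyNA(i)) stop("unknown protein: ",
                       paste(names(counts)[is.na(i)], collapse = ", "))
    pool@counts[i] <- unname(counts)
    validObject(pool)
    pool
}

#' G1-Cdk input constructor
#'
#' @param amplitude maximal activity in molecule counts (default 500).
#' @param midpoint activation midpoint in seconds (default 900 s = 15 min).
#' @param sigma switch-on time scale in seconds (default 180 s).
#' @return A [G1CdkInput-class] object.
#' @export
g1CdkInput <- function(amplitude = 500, midpoint = 900, sigma = 180)
    new("G1CdkInput", amplitude = amplitude, midpoint = midpoint,
        sigma = sigma)

#' G1-Cdk activity at time t
#'
#' Hill-in-time sigmoid, nondecreasing, zero at t = 0, amplitude/2 at the
#' midpoint and saturating at the amplitude.
#'
#' @param t time in seconds (>= 0).
#' @param input G1CdkInput.
#' @param volume nuclear volume for conversion to molar (NULL: counts).
#' @return activity, molecule counts (or molar if volume given).
#' @export
g1cdkActivity <- function(t, input = g1CdkInput(), volume = NULL) {
    if (any(t < 0)) stop("t must be >= 0")
    h <- input@midpoint / input@sigma
    a <- ifelse(t <= 0, 0,
                input@amplitude * t^h / (t^h + input@midpoint^h))
    if (!is.null(volume)) a <- countToMolar(a, volume)
    a
}
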