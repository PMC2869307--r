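---
title: "A kinetic model of replication-origin licensing and firing in budding yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic model of replication-origin licensing and firing in budding yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(RepliNet)
```

## The biological problem

Eukaryotic genomes must replicate completely and exactly once per cell
cycle.  Budding yeast separates this into origin *licensing* in G1 (loading
of the Mcm2-7 helicase onto ORC-marked origins via Cdc6 and Cdt1) and
origin *firing* in S phase (Cdk/Ddk-triggered replisome assembly).  The
kinases that fire origins simultaneously dismantle the licensing machinery
— Cdc6 is degraded after G1-Cdk phosphorylation, free Cdt1 and Mcm2-7 are
exported from the nucleus, and S-Cdk phosphorylates ORC subunits, blocking
Cdt1-dependent Mcm loading.  The network must therefore reconcile two
quantitative demands: fire ~190 early origins rapidly and coherently, yet
keep the probability that any fired origin is relicensed and fired again
(rereplication) vanishingly small.  This package implements the network as
a kinetic model, quantifies both demands, and explores the trade-off
between them.

## Model structure

### State space

Each origin occupies one of ten assembly stages,

S0 (ORC) → S1 (+Cdc6) → S2 (+Cdt1·Mcm) → S3 (pre-RC; Cdc6 and Cdt1
released) → S4 (Mcm phosphorylated) → S5 (+Cdc45) → S6 (+11-3-2 activator)
→ S7 (+GINS·polymerases) → S8 (activator released; replisome) → S9 (fired),

mirrored in an ORC-phosphorylated layer S0P–S9P.  Three structural rules
encode the known biochemistry: inhibitory ORC phosphorylation occurs only
where ORC is exposed — the licensing states S0/S1, where it blocks
licensing, and the fired state S9, where it blocks relicensing — never from
the Cdt1-bound state S2 or the assembled pre-RC/pre-IC states S3–S8;
Cdt1·Mcm loading is blocked in the phosphorylated layer (no S1P → S2P); and
only unphosphorylated fired origins can be relicensed (S9 → S3, gated by
the rate constant k16 and the availability of free Cdc6 and Cdt1·Mcm).
The restriction of ORC phosphorylation to exposed-ORC states is essential
to the model's central tension: were assembled origins able to acquire
protective ORC phosphorylation before firing, every origin would fire
already immune to relicensing and the rereplication constraint could never
limit firing speed.  As implemented, protection of a fired origin is a race
between S9 → S9P (S-Cdk-dependent) and k16 relicensing (licensing-factor
dependent), so firing early — when S-Cdk is still low and Cdc6 still
present — carries a genuine rereplication risk.  The model tracks origin-state *fractions*
(equivalently, per-origin probabilities) coupled to molar free-protein
concentrations; fluxes between the two representations scale with the
molar concentration equivalent of the 190-origin complement (~158 nM in a
2 fL nucleus; 1 molecule ≈ 0.83 nM).

No complete published reaction list exists for this network at the level
of individual rate constants; the chain above is the minimal topology
consistent with the established mechanisms, and is documented as a
reconstruction.
Two mechanisms deliberately omitted: a distinct "loose Cdc45 association"
pre-state, and relicensing of S9P origins after hypothetical ORC
dephosphorylation (no phosphatase acts on ORC within the simulated window).

### Multisite phosphorylation

Sld2 carries six random serine/threonine sites whose phosphorylation
(random-sequential, distributive — one modification per kinase encounter)
exposes the hierarchical Thr84 site; Thr84-phosphorylated Sld2 binds Dpb11.
Sld3 (2 sites) and Sic1 (6 sites) are modelled the same way without a
hierarchical site.  Because per-site kinetics are identical, it suffices to
track the *number* of phosphorylated sites — the collapsed chain is exactly
equivalent to the 2^n microstate model (verified by enumeration for n ≤ 4
in the test suite).  Within the network, per-form Michaelis–Menten rates
are used; the standalone `PhosphoChain` module uses the pseudo-first-order
hazard kcat·E/(Km + c_tot), which keeps the collapsed master equation
linear and admits closed-form oracles (an irreversible n-site chain at
per-site rate k completes in mean time H_n/k).  A processive variant
(single encounter modifies all sites) is provided as the rejected
alternative: it cannot produce the delayed Thr84 time course.

### Inputs and fixed modules

G1-Cdk is an input: a Hill-in-time sigmoid with amplitude 500 molecules,
midpoint 15 min and switch-on scale σ = 3 min (Hill exponent
midpoint/σ).  S-Cdk is *not* an input — it emerges from Sic1 phosphorylation
by G1-Cdk followed by Sic1 degradation, releasing the S-Cdk it
stoichiometrically inhibits.  Ddk is a constant-activity cofactor entering
the Mcm-phosphorylation step additively with S-Cdk; this keeps the step
alive in the constitutive-Sld2/3 scenario, where S-Cdk is sequestered by
non-degradable Sic1 yet firing is experimentally observed.

Licensing and S-Cdk-module rate constants are fixed (not optimized), chosen
to satisfy two experimentally grounded construction conditions:
licensing of early origins completes (~5 min) before S-Cdk becomes active,
and S-Cdk rises with a characteristic delay (~15–20 min) after the G1-Cdk
midpoint.  Within that delay, two calibration choices matter and are
deliberate: the delay is carried by slow Sic1 *degradation*
(8×10⁻⁴ s⁻¹) rather than by the phospho-chain itself (per-site
phosphorylation is fast, 0.5 s⁻¹ at saturation), because reducing Sic1 to a
single phosphosite is reported to leave origin-firing kinetics essentially
unchanged; and the licensing-factor depletion mechanisms (Cdc6 degradation
10⁻³ s⁻¹, Cdt1/Mcm export 5×10⁻⁴ s⁻¹ per normalized kinase activity)
operate on 15–30 min time scales, because it is this slow depletion that
makes a robust delay between S-Cdk activation and firing *necessary* —
minute-scale depletion would abolish the rereplication risk entirely and
with it the central trade-off.

Protein abundances default to the measured pattern: stable replisome
factors at a few thousand copies (Mcm2-7 4000, Cdc45 3000, GINS 3000),
transient factors at a few hundred (Sld2 400, Dpb11 400, S-Cdk 600, Sic1
800), and Sld3 at its strikingly low 130 copies.  Only the Sld3 count is
directly anchored in published measurements; the others are labelled
reconstructions and are overridable.  The scarcity of Sld3 makes catalytic
recycling of the 11-3-2 activator (release at S7 → S8) essential: fewer
activators than origins exist, so stable binding would cap the number of
fired origins.

## Firing statistics

The firing rate f(t) is the instantaneous flux into S9 + S9P, including
refiring.  N = M∫f dt (M = 190), τ and Δ are the first moment and twice the
standard deviation of f, and ρ = N − N₀ counts rereplication events against
a paired run with k16 = 0.  Because optimized firing pulses can be narrower
than any reasonable output grid, the integrator accumulates ∫f, ∫tf and
∫t²f as extra state variables, making these statistics independent of the
output grid; profile-based (trapezoid) equivalents exist for densities
supplied directly.  Moment integrals run to the 3 h horizon (12 h for
random-parameter screening, whose sets fire on multi-hour time scales);
`truncatedMass` reports the terminal-to-peak density ratio as a truncation
diagnostic.

## Parameter search and optimization

Activator- and firing-module constants are sampled log-uniformly from
standard biochemical ranges (association 10⁴–10⁹ M⁻¹s⁻¹, dissociation
10⁻⁴–10² s⁻¹, turnover 10⁻³–10 s⁻¹, Michaelis constants 10⁻⁸–10⁻⁴ M,
relicensing gate 10⁻⁶–10⁻² s⁻¹).  Coherence optimization minimizes Δ
subject to N ≥ 180 and ρ ≤ 0.01 via differential evolution (rand/1/bin,
elitist selection) on the log-scaled parameters, with a quadratic penalty
on the origin-number deficit and a linear penalty on excess rereplication
weighted so that any violation dominates Δ measured in minutes.  Three
disposition choices implement a deliberate strategy of admitting several
local optima rather than hunting the global one: a deliberately
small budget (population 16, ≤ 12 generations, early stop after 6 stagnant
generations), an ensemble assembled from independent runs with different
seeds, and k16 held fixed during optimization — the relicensing propensity
is a property of origin biochemistry, and letting the optimizer shrink it
would dissolve the coherence–rereplication trade-off the constraint is
meant to express.  Fully converged runs drive every rate to its
diffusion-limited bound and produce unrealistically coherent firing
(Δ < 1 min), which is why the budget is part of the model of the procedure,
not a computational shortcut.  The shipped reference fixture
(`inst/extdata/reference_parameters_synthetic.json`, a synthetic
reference set — no measured table of these rate constants exists) is the
ensemble member falling inside the reported admissible bands (τ 40–58 min,
Δ 4–14 min),
regenerable via `regenerateReferenceFixture(seed = 20, nRuns = 8)`.

## Replicon geometry

Origin positions accumulate i.i.d. spacings; the default sampler is a
gamma distribution with mean 46 kb and CV 0.55 — positive and right-skewed,
emulating the measured inter-origin distance distribution (only the mean is
anchored in the text; the CV is the package's fixture choice).  Firing
times are inverse-CDF draws from the simulated density.  Between adjacent
fired origins distance d apart with firing-time difference Δt, forks meet
at (d + vΔt)/2 from the earlier origin (fork speed v = 1.5 kb/min by
default; the text cites a measured speed without printing it).  An origin
is passive if any fork arrives strictly before its own firing time; the
passivity test against all origins is equivalent to the test against fired
origins only (triangle inequality), which the implementation exploits.
Chromosome ends are replicated by the outermost fired origins; replicon
sizes tile the chromosome exactly, and S-phase length runs from first
firing to the last fork meeting or end arrival.  The treatment of ends and
of rereplicated origins reconstructs an unavailable supplement and is a
documented convention.

## Sensitivity analysis

Control coefficients C = d ln R / d ln X for responses R ∈ {N, τ, Δ, ρ} are
central log-differences under ±5% perturbations (2% and 10% available for
convergence checks; both one-sided estimates are reported).  ρ at an
admissible base point can be numerically zero, so its log-derivative is
computed on ρ + 10⁻⁶ origins; coefficients of quantities absent from the
model vanish identically.  Response norms are Euclidean.

## Stochastic validation

Free-protein copy numbers (hundreds to thousands) fluctuate negligibly, so
per-origin stochasticity is simulated as a continuous-time Markov chain
over the origin states with propensities driven by the deterministic
free-protein trajectories.  Event times are drawn exactly by Lewis thinning
against a piecewise majorant of each time-varying rate (1.5× interval
maximum; exceeding it raises a warning).  Mean-field occupancancy marginals
and stochastic ensembles agree within Monte-Carlo error on clamped
constant-rate chains, where thinning is exact.

## Numerical choices

lsoda with rtol 10⁻⁸ and atol 10⁻¹² M is the default; screening and
optimizer inner loops relax to rtol 10⁻⁶ with capped internal steps (5000)
so that pathological random parameter sets fail fast and are classified
infeasible rather than stalling the search.  Negative concentrations are
clipped to zero inside rate laws only.  Optimized winners are re-evaluated
at the tight tolerance before being admitted to an ensemble.

## What the synthetic data do and do not show

All inputs are generated: abundance fixtures, spacing samplers, the G1-Cdk
input and the frozen reference parameter set.  Passing tests demonstrate
internal consistency of the model and pipeline — conservation laws, closed
forms, oracle agreement, the direction and rough magnitude of the mutant
phenotypes — under the reconstructed topology and calibration.  They do not
demonstrate agreement with experimental replication profiles (no
experimental data ship with the package), and quantities that depend on
unknowable kinetic details (the exact functional fraction of random sets,
scenario magnitudes such as the rereplicating percentage under
constitutive Sld2/3) are range- and encoding-sensitive: the mutant
scenarios in particular are reconstructions whose printed reference values
should be read as order-of-magnitude anchors.  Known limitations: no
late-firing origins or chromatin state, no checkpoint signalling, no
cell-to-cell variability beyond scenario overrides, and a mean-field
description of free proteins.

## Problem sizes

The shipped analyses use 190 origins, 200-draw screens over a 12 h horizon,
ensembles of 4–8 optimizer runs, and 10³–10⁴-draw Monte-Carlo checks —
sizes at which the full pipeline (screen, optimize, scenarios) completes in
roughly a quarter of an hour on a single core while leaving the ensemble
statistics stable enough to compare against reported measurements.
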