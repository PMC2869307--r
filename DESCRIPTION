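Package: RepliNet
Title: Kinetic Modelling of DNA Replication Initiation in Budding Yeast
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mean-field and stochastic simulation of the molecular network
    that licenses and fires DNA replication origins in Saccharomyces
    cerevisiae. The package integrates the four-module origin-activation
    network (origin licensing, S-Cdk activation through Sic1 degradation,
    assembly of the Dpb11-Sld3-Sld2 (11-3-2) activator by distributive
    multisite phosphorylation, and origin firing), computes firing-rate
    statistics (number of fired origins, rereplication, mean firing time and
    firing duration), maps firing-time densities onto replicon geometries,
    performs constrained differential-evolution optimization of firing
    coherence over biochemically feasible parameter ranges, control-coefficient
    sensitivity analysis, and the standard perturbation scenarios (slow Sic1
    degradation, sic1 deletion, constitutive Sld2/Sld3, S-Cdk titration and
    phosphosite-number variation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, deSolve, jsonlite
Suggests: testthat (>= 3.0.0), Matrix, yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
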