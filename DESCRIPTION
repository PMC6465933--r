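Package: idpbiophys
Title: Biophysical Analysis of Intrinsically Disordered Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative tools for characterizing intrinsically disordered
    proteins (IDPs) and their complexes with folded domains, built around the
    workflow used to study the periaxin C-terminal region bound to the
    beta4-integrin FNIII-3 domain. Provides random-chain polymer scaling laws
    (radius of gyration and end-to-end distance from residue count),
    coarse-grained conformer ensemble generators (freely jointed and
    self-avoiding chains, compact globule mimics, tethered chain-domain
    complexes), forward small-angle X-ray scattering via the Debye equation,
    Guinier and Debye-formalism (Calmettes) radius-of-gyration estimators,
    dimensionless Kratky transforms, pair-distance distributions, a genetic
    algorithm for ensemble optimization against scattering data, one-site
    isothermal titration calorimetry simulation and nonlinear fitting,
    two-state thermal melt simulation with derivative-peak melting-temperature
    extraction, and protein mass/stoichiometry bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    minpack.lm,
    signal,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
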