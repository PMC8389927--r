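Package: igft
Title: Interpolated Gaussian Fluctuation Theory for Cavity Solvation Thermodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analytic modelling of solvent occupancy fluctuations in
    microscopic observation volumes and the hydration thermodynamics of
    hard-sphere solutes.  The normalized occupancy variance is bridged from
    its exact microscopic form to the macroscopic compressibility
    (Kirkwood-Buff) limit by a smooth cubic-in-1/R interpolation driven
    only by the solvent equation of state and an effective solvent
    diameter.  Gaussian and two-moment maximum-entropy occupancy
    distributions convert fluctuations into excess chemical potentials,
    and a temperature decomposition yields hydration enthalpies,
    entropies, heat capacities, solubility-minimum and
    entropy-convergence temperatures.  Widom-style probe insertion into
    synthetic ideal-gas and hard-sphere fluid configurations provides
    brute-force validation of every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
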