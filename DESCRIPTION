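Package: neqswitch
Title: Non-Equilibrium Work Switching Free Energies Between Two Levels of
    Theory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes free energy differences between a low ("MM"-like) and a
    high ("QM/MM"-like) level of theory from non-equilibrium work switching
    simulations. Implements the Jarzynski exponential-average estimator, the
    two-sided Crooks/Bennett acceptance-ratio estimator, and staged BAR over
    charge-interpolated intermediate states, together with linear and
    stepwise-linear switching schedules, hybrid charge intermediate states
    obtained by averaging configuration-dependent high-level charges, and
    convergence diagnostics (work-distribution overlap, charge-distribution
    metrics, first-solvation-shell counts, and Stokes-shift relaxation
    analysis). Ships toy dual-level model systems -- a harmonic pair with a
    closed-form free energy and a rigid polarizable-charge solute in a bath
    of dipolar rotors evolved by Langevin dynamics -- that serve as exact or
    brute-force oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
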