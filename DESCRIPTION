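Package: phzfmech
Title: Mechanism Discrimination for the PhzF-Catalyzed Isomerization of DHHA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discriminate competing catalytic mechanisms of the
    phenazine-biosynthesis isomerase PhzF on surrogate energy surfaces.
    Provides reaction-path optimization (nudged elastic band with climbing
    image, conjugate peak refinement), Hessian-based stationary-point
    classification and harmonic frequencies, multi-site protonation-state
    Metropolis Monte Carlo titration with an exact enumeration oracle,
    transition-state-theory rates and kinetic-isotope-effect calculators
    from zero-point energies, photometric enzyme-assay simulation with
    Michaelis-Menten fitting and apparent-KIE extraction, and assembly and
    ranking of catalytic-cycle free-energy profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    deSolve,
    minpack.lm,
    jsonlite,
    bio3d,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
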