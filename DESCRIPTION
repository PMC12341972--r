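Package: pcoflux
Title: Pathway-Controlled Optimization of Metabolic Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts metabolic regulation that maximizes flux through
    designated growth reactions while holding metabolite concentrations at
    physiological levels. Fluxes follow the maximum-path-entropy (Marcelin)
    thermodynamic flux law, in which each reaction rate is proportional to
    its thermodynamic force and is scaled by an enzyme activity coefficient
    in [0,1]. The pathway-controlled optimization (PCO) problem is solved in
    log-concentration space with a nullspace parameterization of steady-state
    fluxes, a big-M relaxation of the flux-direction switching conditions,
    and an interior-point (log-barrier) solver with a feasibility-oriented
    initialization. A metabolic-control-analysis (MCA) baseline that
    regulates activities only to cap concentrations is included for
    comparison, together with generators for thermodynamically consistent
    toy networks and a brute-force optimization oracle for small instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    deSolve,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
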