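Package: riemcv
Title: Riemannian Analysis of Collective-Variable Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coordinate-invariant thermodynamics and kinetics on
    collective-variable (CV) spaces treated as Riemannian manifolds.
    Provides invariant potentials of mean force corrected by the induced
    metric tensor, overdamped Langevin simulation with Christoffel drift
    on curved CV spaces, zero-temperature string computation of minimum
    free energy paths, metric-generalized tridiagonal Smoluchowski rate
    matrices with maximum-likelihood estimation of free energy and metric
    profiles from lagged transition counts, and mean first passage times
    by closed-form quadrature and absorbing-boundary linear solves.
    Includes analytic benchmark systems (a one-dimensional quadratic
    potential and the Mueller-Brown surface) and a config-driven command
    line pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
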