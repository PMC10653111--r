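Package: neqfe
Title: Work-Based Estimators and Convergence Diagnostics for Alchemical
    Relative Binding Free Energies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis machinery for equilibrium and nonequilibrium alchemical
    relative binding free energy calculations. Provides work-based free energy
    estimators (Jarzynski, Crooks Gaussian intersection, Bennett acceptance
    ratio), ensemble-averaged thermodynamic integration over lambda windows,
    the forward/reverse work-distribution overlap coefficient, replica,
    transition-count and simulation-time convergence diagnostics,
    prediction-versus-experiment benchmark metrics with bootstrap errors,
    lambda-schedule and protocol cost accounting, and a synthetic-data
    generator that emulates the statistical structure of ensemble molecular
    dynamics outputs so the full pipeline can be exercised without running
    any molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
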