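Package: spectralUQ
Title: Spectral-Expansion Surrogate Models for Uncertainty Quantification in Systems Biology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-intrusive spectral-expansion (polynomial chaos) surrogate
    models for propagating parameter uncertainty through deterministic
    biological models. Expansion coefficients are obtained from the
    eigendecomposition of the Jacobi-type matrix of the multiplication
    operator in an orthonormal basis (Legendre, Hermite, Charlier, or Haar
    wavelets on a CDF), so a model with M uncertain parameters and order-N
    expansion needs only N^M deterministic runs. Includes interval
    segmentation for piecewise low-order expansions, Haar-wavelet bases for
    responses with bifurcations, a correlated-parameter scheme built on a
    bivariate Poisson uptake distribution, Sobol sensitivity indices read
    off the expansion coefficients, a quasi-Monte-Carlo reference engine
    (Sobol sequences, blocking-method error bars, kernel density
    estimation), and six worked example systems from enzyme kinetics,
    oscillatory glycolysis, reaction-diffusion patterning, and plasmid
    transfection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
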