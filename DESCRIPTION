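Package: opvar
Title: Ordinal Pattern Analysis with Magnitude Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinal-pattern (Bandt-Pompe) analysis of univariate signals in
    which the permutation entropy and Renyi min-entropy of the ordinal-pattern
    sequence are complemented by the ordinal-pattern-averaged logarithm of the
    standard deviation of the signal magnitudes inside the embedded vectors.
    Includes simulators for coupled logistic maps and the Henon map with
    optional additive observational noise, maximum-Lyapunov-exponent
    estimation (analytic-Jacobian Benettin iteration and Wolf's
    nearest-neighbour divergence tracking), and a power-law scaling analysis
    of the magnitude variability over embedding dimensions that separates
    deterministic from noise-dominated signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
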