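Package: darpac
Title: Driven Auto-Regressive Models for Phase-Amplitude Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection, quantification and characterization of phase-amplitude
    coupling (PAC) in univariate neural time series using driven auto-regressive
    (DAR) models. An AR model whose coefficients and innovation variance are
    polynomial functions of a slow, band-limited, complex-valued driver yields a
    driver-conditional power spectrum, a likelihood for principled selection of
    filtering parameters and model orders, comodulograms based on a normalized
    Kullback-Leibler modulation metric, coupling-delay estimation from forward
    and time-reversed fits, classical PAC baselines (Tort, Ozkurt, Penny), a PAC
    signal simulator, and surrogate-based significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    withr,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
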