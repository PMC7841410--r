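Package: doinfo
Title: Dynamic O-Information for Higher-Order Dynamical Influences in
    Multivariate Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies redundant and synergistic higher-order dynamical
    influences of groups of time series (multiplets) on a target series via
    the dynamic O-information, a past-conditioned multivariate extension of
    the interaction information. Provides Gaussian-copula and discrete
    plug-in estimators of entropy and (conditional) mutual information in
    bits, pairwise and global transfer entropy, greedy multiplet search
    with circular-shift surrogate significance testing, an exactly solvable
    four-variable binary benchmark system, and a synthetic spiking-raster
    generator with planted informational circuits for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
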