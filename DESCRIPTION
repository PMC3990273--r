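Package: levelxing
Title: Coordinated Threshold Crossings of Correlated Gaussian Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistics of coordinated threshold upcrossings ("spikes") of two
    cross-correlated stationary Gaussian processes. Implements the Rice
    upcrossing rate, the closed-form conditional-rate series obtained from a
    regression model and Mehler's formula, the exact zero-lag coincidence
    rate, a Taylor expansion in the correlation strength, and the Hermite
    chaos expansion of the bivariate central limit theorem for upcrossing
    counts (asymptotic count variances, covariance and Pearson coefficient).
    Includes an exact circulant-embedding simulator for correlated Gaussian
    voltage pairs with shared and private noise, empirical estimators that
    mirror every theoretical quantity, and a joint-Gaussianity test battery
    (projection normality and Mahalanobis distance against the chi-squared
    law). Quadrature oracles are provided alongside every series so that each
    closed form can be validated independently.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
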