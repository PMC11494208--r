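Package: mindful
Title: Unsupervised Drift Monitoring for Intracortical Brain-Computer
    Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify model drift in chronic intracortical
    brain-computer interface (iBCI) recordings without access to movement
    intention labels.  The central statistic (the MINDFUL score) is the
    closed-form Kullback-Leibler divergence between a multivariate
    Gaussian summary of derived neural features collected during an epoch
    of known good decoding and Gaussian summaries of sliding comparison
    windows.  The package also provides the validation machinery around
    the score: angle-error performance metrics, angle-error-binned
    divergence, per-feature cosine-tuning drift with bootstrap change
    detection, population tuning-map similarity, direction-dependent
    latent-subspace variance accounted for, and a synthetic closed-loop
    cursor-BCI simulator with parameterised session-to-session drift so
    every analysis stage can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    arrow,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
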