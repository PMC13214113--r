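Package: betavigor
Title: Beta-Band Coherence and Power as Trial-Level Predictors of Movement Vigor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline comparing seed-based beta-band imaginary
    coherence and local beta power as predictors of movement vigor in
    epoched electrophysiological recordings. Provides a synthetic cohort
    generator with planted coupling, power and behavioral effects; kinematic
    feature extraction from luxmeter and accelerometer traces; Morlet and
    filter-Hilbert spectral features; symmetric orthogonalization and
    per-trial seed-based imaginary coherence; MAD trial screening and
    cluster-based spatial permutation tests; grouped sequential forward
    selection around L1-regularized logistic decoding with bootstrap
    stability; and group-level consistency and vigor-correlation inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    pracma,
    signal,
    stats,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
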