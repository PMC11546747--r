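Package: operantNeuro
Title: Reward-Seeking Operant Behavior and Accumbens Neural Signal Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for rodent reward-seeking experiments combining
    operant task simulation (fixed-ratio, progressive-ratio, demand, and
    go/no-go schedules), fiber-photometry dopamine signal processing
    (isosbestic detrending, peri-event z-scored PSTHs, transient detection),
    single-unit encoding-pattern discovery by iterative k-means, canonical
    polyadic (CP) decomposition of unit x trial x time tensors with cross-run
    rank selection, exponential demand-curve economics (Q0, alpha, Pmax,
    essential value), Bayesian logistic regression with a compound confluent
    hypergeometric prior for encoding-bias inference, and PCA-based behavioral
    endophenotyping. Includes seeded synthetic-data generators with planted
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
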