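Package: sfnet
Title: Scale-Free Classification of Biochemical Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Projects biochemical reaction datasets (genome- or
    metagenome-scale lists of reactions with substrate and product
    compounds) into eight network representations, fits discrete power
    laws to their degree distributions with Kolmogorov-Smirnov selection
    of the lower cutoff and a semi-parametric bootstrap goodness-of-fit
    test, compares the power law against four alternative heavy-tailed
    distributions by likelihood-ratio tests, classifies each dataset on
    the Super-Weak to Strongest scale-free ladder, and tests whether
    individual-level (genome) and ecosystem-level (metagenome) networks
    can be told apart from degree-distribution features using balanced
    logistic models and random forests. Includes a seeded synthetic
    reaction-data generator so the full pipeline is testable without
    database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    randomForest,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
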