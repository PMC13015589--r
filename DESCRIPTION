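Package: operantPheno
Title: Operant Learning Analysis and Multidimensional Phenotyping for
    Mouse Behavioral Batteries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for scoring operant acquisition and extinction sessions
    in mouse models of Angelman syndrome (trial counts, cued-response
    accuracy, days-to-criteria, acquisition-normalized extinction curves),
    for multidimensional phenotyping of behavioral batteries via
    z-standardization, principal component analysis and k-means genotype
    clustering (including a PC1 composite severity score and genotype
    centroid distances), and for bootstrap power analysis to plan per-group
    sample sizes across measures. A seeded synthetic-cohort generator
    emulating the two-genotype, two-sex, two-cohort study design makes the
    whole pipeline testable end to end without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
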