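Package: spatialdiv
Title: Genetic Diversity Measures and Their Estimation Under Spatial Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes classical genetic diversity measures (expected
    heterozygosity, nucleotide diversity, Watterson's theta) and a
    frequency-independent measure, the average substitution rate among
    allele types (final sigma), from aligned nucleotide sequences.
    Provides geographically even selection of sampling locations by
    simulated annealing over GRS80 geodesic distances, a structured
    coalescent simulator with stepping-stone and island migration, a GTR
    sequence mutation engine, and an experiment engine that quantifies
    estimator bias (scaled mean error) and accuracy (scaled root mean
    square error) when individuals are collected one per location under
    spatial sampling instead of random sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
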