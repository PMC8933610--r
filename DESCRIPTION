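Package: setscape
Title: Multi-Trait Coadaptation Analysis Along Population Range Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exploratory analysis of multi-trait coadaptation in structured
    populations. Provides a forward simulator of one-dimensional
    stepping-stone colonization with polygenic environmental selection,
    matching-based population-specific FST, correspondence analysis of
    composite population-by-(SNP, trait, environment) tables, per-trait
    association scans with genotype-environment correlation tests, a
    drift-covariance admixture-graph fit with a standardized per-edge
    polygenic selection statistic, and principal component analysis of the
    selection-on-edge-by-trait (SET) matrix including factor loadings of
    environmental variables. Reads Genepop genotype files and writes
    TreeMix-compatible allele-count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
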