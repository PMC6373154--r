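Package: etfcrossfeed
Title: Gene-Neighbourhood Mining and Fermentation Balances for Lactate
    Cross-Feeding Butyrate Producers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying lactate cross-feeding in anaerobic
    butyrate-producing Firmicutes. Locates electron-transferring
    flavoprotein (etfA/etfB) gene pairs in annotated genomes, classifies
    their gene-neighbourhood context (lactate oxidation versus butyrate
    formation), builds progressive protein alignments and UPGMA trees with
    Jukes-Cantor corrected distances and bootstrap support, tests whether
    Etf complexes cluster by catalysed reaction rather than by species,
    and converts batch fermentation concentration tables into carbon and
    electron balances over an electron-bifurcating reaction network.
    Includes seeded generators for annotated replicons with planted gene
    clusters, protein families evolved along known trees, and fermentation
    tables derived from known flux vectors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    pracma,
    purrr,
    Rcpp,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
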