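Package: nearzero
Title: Retentostat Kinetics and Growth-Rate-Dependent Transcriptome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of microbial physiology at near-zero specific growth
    rates. Implements the retentostat maintenance-energy kinetic model
    (biomass accumulation, exponential curve fitting, viability-corrected
    specific growth rates, glucose partitioning between maintenance and
    growth), microarray-style expression preprocessing (global scaling,
    intensity flooring, low-signal filtering, mean-normalized profiles),
    a spline-based permutation F-test for growth-rate-dependent expression
    with Storey q-values, k-means clustering under a positive-correlation
    distance, hypergeometric gene-set enrichment, IUPAC promoter-motif
    scanning with enrichment factors, and a synthetic-data generator that
    emulates a combined chemostat plus retentostat microarray design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    splines,
    utils,
    jsonlite,
    Biostrings,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
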